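# Responder-gene signature derivation: in-vitro stimulation filter,
# intersection with the spatial DEG list, cross-signature purification,
# and literature supplementation.

#' Default stimulation fold-change thresholds
#'
#' log2 fold-change cutoffs for the in-vitro filter: 1.5 for IFNG and
#' IL17A, 1 for IL13 (the weaker keratinocyte IL-13 response warrants the
#' lower bar); any other cytokine defaults to 1.5.
#'
#' @param cytokines Cytokine names.
#' @return Named numeric vector of thresholds.
#' @export
default_fc_cuts <- function(cytokines = default_cytokines()) {
  setNames(ifelse(cytokines == "IL13", 1.0, 1.5), cytokines)
}

#' Read a stimulation DEG table from CSV
#'
#' Expected columns: `gene`, `cytokine`, `log2fc`, `p_value`,
#' `adj_p_value` (one row per gene x cytokine).
#'
#' @param path CSV path.
#' @return A `stim_deg_table` data frame.
#' @export
read_stim_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "cytokine", "log2fc", "p_value", "adj_p_value")
  .assert(all(need %in% names(tab)), "stimulation table missing columns: %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  .assert(!anyDuplicated(tab[, c("gene", "cytokine")]),
          "duplicate (gene, cytokine) rows in stimulation table")
  class(tab) <- c("stim_deg_table", "data.frame")
  tab
}

#' Filter the stimulation table for one cytokine
#'
#' Keeps genes with `p_value < p_cut`, `adj_p_value < padj_cut` and
#' `log2fc > fc_cut` (strict inequalities throughout).
#'
#' @param stim A `stim_deg_table`.
#' @param cytokine Cytokine name (must occur in the table).
#' @param fc_cut log2FC threshold; defaults to [default_fc_cuts()] for the
#'   cytokine.
#' @param p_cut,padj_cut P-value thresholds (default 0.05 each).
#' @return Sorted character vector of passing genes.
#' @export
filter_stim_deg <- function(stim, cytokine, fc_cut = NULL, p_cut = 0.05,
                            padj_cut = 0.05) {
  .assert(cytokine %in% stim$cytokine,
          "unknown cytokine in stimulation table: %s", cytokine)
  if (is.null(fc_cut)) fc_cut <- unname(default_fc_cuts(cytokine))
  sub <- stim[stim$cytokine == cytokine, , drop = FALSE]
  keep <- sub$log2fc > fc_cut & sub$p_value < p_cut & sub$adj_p_value < padj_cut
  sort(unique(sub$gene[keep]))
}

#' Responder signature container
#'
#' @param cytokine Cytokine name.
#' @param genes Gene symbols.
#' @param provenance Per-gene provenance, `"in_vitro∩spatial"` or
#'   `"literature"` (recycled).
#' @return Object of class `responder_signature`.
#' @export
responder_signature <- function(cytokine, genes,
                                provenance = "in_vitro∩spatial") {
  genes <- as.character(genes)
  .assert(!anyDuplicated(genes), "duplicate genes in signature")
  structure(list(cytokine = cytokine, genes = genes,
                 provenance = setNames(rep_len(provenance, length(genes)),
                                       genes)),
            class = "responder_signature")
}

#' @export
print.responder_signature <- function(x, ...) {
  cat(sprintf("responder_signature %s: %d gene(s) (%d literature)\n",
              x$cytokine, length(x$genes),
              sum(x$provenance == "literature")))
  invisible(x)
}

#' Intersect stimulation-derived genes with the spatial DEG list
#'
#' The in-vitro response is grounded in vivo by keeping only genes also
#' called in the spatial contrast of cytokine-positive epidermal spots
#' versus negative ones.
#'
#' @param stim_genes Character vector from [filter_stim_deg()].
#' @param spatial Either a character vector of spatially significant
#'   genes or a DEG table (then filtered via [call_degs()] with its
#'   defaults).
#' @param cytokine Cytokine name for the resulting signature.
#' @return A [responder_signature()] (possibly empty, with a warning).
#' @export
intersect_with_spatial <- function(stim_genes, spatial, cytokine) {
  spatial_genes <- if (is.character(spatial)) spatial else call_degs(spatial)
  genes <- sort(intersect(stim_genes, spatial_genes))
  if (length(genes) == 0) {
    warning("empty intersection of stimulation and spatial DEG lists for ",
            cytokine, call. = FALSE)
  }
  responder_signature(cytokine, genes)
}

#' Cross-signature purification
#'
#' Removes every gene appearing in two or more candidate signatures from
#' all of them, leaving pairwise disjoint signatures.  Idempotent and
#' independent of list order.
#'
#' @param sigs List of [responder_signature()] objects.
#' @return List of purified signatures (same order).
#' @export
purify_signatures <- function(sigs) {
  stopifnot(all(vapply(sigs, inherits, TRUE, "responder_signature")))
  counts <- table(unlist(lapply(sigs, `[[`, "genes")))
  shared <- names(counts)[counts >= 2]
  lapply(sigs, function(s) {
    keep <- setdiff(s$genes, shared)
    responder_signature(s$cytokine, keep, unname(s$provenance[keep]))
  })
}

#' Supplement a signature with literature-derived genes
#'
#' Adds a configured list of well-established responder genes (used for
#' IL-13, whose data-derived signature is small), recording `"literature"`
#' provenance.  Duplicates of existing members are collapsed; a literature
#' gene already present in another cytokine's signature is an error, since
#' it would break the pairwise disjointness established by purification.
#'
#' @param sig A [responder_signature()].
#' @param literature_genes Character vector of genes to add.
#' @param other_sigs Other cytokines' signatures, checked for collisions.
#' @return The augmented signature.
#' @export
add_literature_genes <- function(sig, literature_genes, other_sigs = list()) {
  stopifnot(inherits(sig, "responder_signature"))
  literature_genes <- unique(as.character(literature_genes))
  clash <- intersect(literature_genes,
                     unlist(lapply(other_sigs, `[[`, "genes")))
  .assert(length(clash) == 0,
          "literature gene(s) collide with another signature: %s",
          paste(clash, collapse = ", "))
  new <- setdiff(literature_genes, sig$genes)
  responder_signature(sig$cytokine, c(sig$genes, new),
                      c(unname(sig$provenance),
                        rep("literature", length(new))))
}

#' Derive all responder signatures from a stimulation table
#'
#' The full cascade per cytokine: in-vitro filter, intersection with the
#' spatial DEG list, cross-signature purification, then literature
#' supplementation.
#'
#' @param stim A `stim_deg_table`.
#' @param spatial_lists Named list (per cytokine) of character vectors of
#'   spatially significant genes, or DEG tables.
#' @param cytokines Cytokines to process (default: those in
#'   `spatial_lists`).
#' @param fc_cuts Named thresholds (default [default_fc_cuts()]).
#' @param literature Named list of literature gene vectors to add after
#'   purification (e.g. `list(IL13 = c(...))`).
#' @return Named list of [responder_signature()] objects.
#' @export
derive_signatures <- function(stim, spatial_lists,
                              cytokines = names(spatial_lists),
                              fc_cuts = default_fc_cuts(cytokines),
                              literature = list()) {
  sigs <- lapply(cytokines, function(cy) {
    stim_genes <- filter_stim_deg(stim, cy, fc_cut = fc_cuts[[cy]])
    intersect_with_spatial(stim_genes, spatial_lists[[cy]], cy)
  })
  sigs <- purify_signatures(sigs)
  names(sigs) <- cytokines
  for (cy in intersect(names(literature), cytokines)) {
    sigs[[cy]] <- add_literature_genes(sigs[[cy]], literature[[cy]],
                                       sigs[setdiff(cytokines, cy)])
  }
  sigs
}

#' Write signatures to JSON
#'
#' @param sigs Named list of [responder_signature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path) {
  obj <- lapply(sigs, function(s)
    list(cytokine = s$cytokine, genes = s$genes,
         provenance = as.list(s$provenance)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
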