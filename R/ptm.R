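#' Cell marks
#'
#' Manual cell annotations: the world coordinate of each marked nucleus
#' centroid plus its cell-type term. Stored as a data frame with columns
#' `x_um`, `y_um`, `z_um`, `ct_term`.
#'
#' @param x_um,y_um,z_um Numeric coordinates (um), finite.
#' @param ct_term Character cell-type term ids, non-empty.
#' @return A `cell_marks` data frame.
#' @export
cell_marks <- function(x_um, y_um, z_um, ct_term) {
  stopifnot(all(is.finite(x_um)), all(is.finite(y_um)), all(is.finite(z_um)),
            all(nzchar(ct_term)))
  structure(data.frame(x_um = x_um, y_um = y_um, z_um = z_um,
                       ct_term = as.character(ct_term)),
            class = c("cell_marks", "data.frame"))
}

#' @rdname cell_marks
#' @param path CSV path with columns x_um, y_um, z_um, ct_term.
#' @export
read_cell_marks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cell_marks(df$x_um, df$y_um, df$z_um, df$ct_term)
}

#' @rdname cell_marks
#' @param marks A `cell_marks` data frame to write.
#' @export
write_cell_marks <- function(marks, path) {
  write.csv(as.data.frame(marks), path, row.names = FALSE)
  invisible(path)
}

#' Assign cells to pFTU diffusive fields
#'
#' A cell belongs to every pFTU whose voxel set contains the voxel of its
#' nucleus centroid; in general cells are members of multiple pFTUs,
#' because neighbouring diffusive fields overlap. Marks outside the
#' volume (or in no pFTU) are recorded as unassigned.
#'
#' @param marks A [cell_marks()] data frame.
#' @param pftus List of [pftu_domain()].
#' @param vol The [labeled_volume()] grid the pFTUs live on.
#' @return A `cell_membership` list: `membership` (per cell, character
#'   vector of pftu ids), `unassigned` (cell row indices). Out-of-bounds
#'   marks trigger a warning.
#' @export
assign_cells <- function(marks, pftus, vol) {
  pts <- as.matrix(as.data.frame(marks)[, c("x_um", "y_um", "z_um")])
  vox <- world_to_vox(pts, vol)
  if (anyNA(vox))
    warning(sum(is.na(vox)), " cell mark(s) outside the volume bounds")
  membership <- vector("list", nrow(pts))
  for (p in pftus) {
    inside <- !is.na(vox) & vox %in% p$voxels
    for (i in which(inside))
      membership[[i]] <- c(membership[[i]], p$pftu_id)
  }
  for (i in seq_along(membership))
    if (is.null(membership[[i]])) membership[[i]] <- character(0)
  structure(list(membership = membership,
                 unassigned = which(lengths(membership) == 0)),
            class = "cell_membership")
}

#' @export
print.cell_membership <- function(x, ...) {
  cat(sprintf("cell membership: %d cells, %d unassigned, %d multi-member\n",
              length(x$membership), length(x$unassigned),
              sum(lengths(x$membership) > 1)))
  invisible(x)
}

#' Primary tissue motifs
#'
#' The pairing of an anatomy term with the non-redundant set of distinct
#' cell-type terms found within one diffusive field.
#'
#' @param anatomy_term Anatomy term (or id string); always present.
#' @param cell_types Character vector of cell-type term ids (deduplicated,
#'   sorted; may be empty).
#' @param pftu_id Optional originating pFTU id.
#' @param n_cells_by_type Optional named counts of member cells per type.
#' @return A `primary_tissue_motif` object.
#' @export
primary_tissue_motif <- function(anatomy_term, cell_types = character(0),
                                 pftu_id = NULL, n_cells_by_type = NULL) {
  structure(list(anatomy_term = term_id(anatomy_term),
                 cell_types = sort(unique(as.character(cell_types))),
                 pftu_id = pftu_id,
                 n_cells_by_type = n_cells_by_type),
            class = "primary_tissue_motif")
}

#' @export
print.primary_tissue_motif <- function(x, ...) {
  cat(sprintf("PTM [%s]: {%s}\n", x$anatomy_term,
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Derive the primary tissue motif of a pFTU
#'
#' The PTM is the pFTU's anatomy term plus the deduplicated cell-type
#' terms of its member cells. Order of marks is immaterial (set
#' semantics); an empty membership yields an empty cell-type set with the
#' anatomy term retained.
#'
#' @param pftu A [pftu_domain()].
#' @param membership A `cell_membership` from [assign_cells()].
#' @param marks The [cell_marks()] used for the membership.
#' @return A [primary_tissue_motif()].
#' @export
derive_ptm <- function(pftu, membership, marks) {
  member <- which(vapply(membership$membership,
                         function(m) pftu$pftu_id %in% m, logical(1)))
  cts <- as.data.frame(marks)$ct_term[member]
  counts <- if (length(cts)) table(cts) else NULL
  primary_tissue_motif(
    anatomy_term = if (is.null(pftu$anatomy_term)) "unspecified"
                   else pftu$anatomy_term,
    cell_types = cts, pftu_id = pftu$pftu_id,
    n_cells_by_type = if (is.null(counts)) NULL
                      else as.list(stats::setNames(as.integer(counts),
                                                   names(counts))))
}

#' Check a cell-model annotation against a PTM
#'
#' Combining cell-specific models to study tissue-level processes is
#' legitimate only when the modelled cells are provably within diffusion
#' distance in the same pFTU: the model's anatomy term must match the
#' PTM's, and every cell-type term the model requires must be present in
#' the PTM's cell-type set.
#'
#' @param ptm A [primary_tissue_motif()].
#' @param model_annotations List with `anatomy_term` and `cell_types`.
#' @return List: `compatible` (logical) and `reasons` (character vector
#'   naming the anatomy mismatch and/or each missing cell-type term;
#'   empty when compatible).
#' @export
ptm_compatible <- function(ptm, model_annotations) {
  reasons <- character(0)
  if (!identical(term_id(model_annotations$anatomy_term), ptm$anatomy_term))
    reasons <- c(reasons, "anatomy_term")
  missing <- setdiff(vapply(model_annotations$cell_types, term_id,
                            character(1)),
                     ptm$cell_types)
  reasons <- c(reasons, missing)
  list(compatible = length(reasons) == 0, reasons = unname(reasons))
}

#' Write PTMs to JSON
#'
#' @param ptms List of [primary_tissue_motif()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ptms <- function(ptms, path) {
  obj <- lapply(ptms, function(p)
    list(pftu_id = p$pftu_id, fma_term = p$anatomy_term,
         ct_terms = as.list(p$cell_types),
         n_cells_by_type = p$n_cells_by_type))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
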