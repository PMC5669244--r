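#' Residue-surface contact definition
#'
#' Per-residue distance cutoffs derived from the van der Waals extent of the
#' residue's reference side-chain atom plus the gold atom radius plus a
#' tolerance. A residue is in contact when the minimum height of its reference
#' atoms above the surface plane is at or below its cutoff.
#'
#' @param cutoffs named numeric vector of per-residue cutoffs, nm (> 0).
#' @param reference_atoms optional named list of reference atom names (for
#'   bookkeeping; the slab frames already carry resolved reference atoms).
#' @param surface_plane gold top-layer height, nm; when `NA`, each frame's own
#'   `gold_top_z` is used.
#' @return an object of class `contact_definition`.
#' @export
#' @examples
#' cd <- contact_definition(c(TRP1 = 0.45, ALA2 = 0.40))
contact_definition <- function(cutoffs, reference_atoms = NULL,
                               surface_plane = NA_real_) {
  stopifnot(is.numeric(cutoffs), all(cutoffs > 0),
            !is.null(names(cutoffs)), all(names(cutoffs) != ""))
  structure(list(cutoffs = cutoffs, reference_atoms = reference_atoms,
                 surface_plane = surface_plane),
            class = "contact_definition")
}

#' Default contact cutoff from van der Waals radii
#'
#' `cutoff = r_vdw(reference atom) + r_vdw(Au) + tolerance`, with a gold radius
#' of 0.166 nm and a default tolerance of 0.05 nm.
#'
#' @param r_vdw van der Waals radius of the side-chain reference atom, nm.
#' @param r_gold gold atom van der Waals radius, nm.
#' @param tolerance additive tolerance, nm.
#' @return cutoff, nm.
#' @export
vdw_cutoff <- function(r_vdw, r_gold = 0.166, tolerance = 0.05) {
  r_vdw + r_gold + tolerance
}

#' Per-residue contact booleans for one frame
#'
#' A residue is in contact iff the minimum over its reference atoms of
#' `z - surface_plane` is at or below its cutoff (boundary included).
#'
#' @param frame a [slab_frame()].
#' @param definition a [contact_definition()].
#' @return named logical vector over the residues in the definition.
#' @export
contact_vector <- function(frame, definition) {
  plane <- if (is.na(definition$surface_plane)) frame$gold_top_z
           else definition$surface_plane
  res <- names(definition$cutoffs)
  missing <- setdiff(res, names(frame$residue_refs))
  if (length(missing))
    stop("residue(s) missing from frame: ", paste(missing, collapse = ", "))
  out <- vapply(res, function(r) {
    min(frame$residue_refs[[r]][, 3]) - plane <= definition$cutoffs[[r]]
  }, TRUE)
  names(out) <- res
  out
}

#' Contact strength class from a contact probability
#'
#' Upper-closed bins: p <= 0.25 `none`, (0.25, 0.50] `moderate`,
#' (0.50, 0.75] `significant`, (0.75, 1] `strong`.
#'
#' @param p contact probabilities in \[0, 1\].
#' @return character vector of classes.
#' @export
contact_class <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  cut(p, breaks = c(-Inf, 0.25, 0.50, 0.75, 1),
      labels = c("none", "moderate", "significant", "strong"),
      right = TRUE) |> as.character()
}

#' Re-weighted residue-surface contact probabilities
#'
#' `p_r = sum_t W(t) contact_r(t)` over the supplied (bound-state) frames,
#' classified into contact-strength classes, plus the mean number of residues
#' simultaneously in contact, `sum_t W(t) n_contacts(t)` (which equals
#' `sum_r p_r` exactly).
#'
#' @param frames list of [slab_frame()] objects (bound-state frames).
#' @param weights a [frame_weights()] aligned with `frames`, or `NULL` for
#'   uniform weights.
#' @param definition a [contact_definition()].
#' @return a data frame of class `contact_table` with columns `residue`, `p`,
#'   `class`, and attributes `mean_simultaneous` and `scheme`.
#' @export
contact_probabilities <- function(frames, weights = NULL, definition) {
  n <- length(frames)
  if (n == 0) stop("empty bound-state frame set")
  W <- if (is.null(weights)) rep(1 / n, n) else weights$W
  if (length(W) != n) stop("weights not aligned with frames")
  W <- W / sum(W)
  cm <- vapply(frames, contact_vector, definition = definition,
               FUN.VALUE = logical(length(definition$cutoffs)))
  cm <- matrix(cm, nrow = length(definition$cutoffs))  # residues x frames
  p <- pmin(pmax(as.vector(cm %*% W), 0), 1)  # guard fp rounding at 0/1
  names(p) <- names(definition$cutoffs)
  mean_sim <- sum(colSums(cm) * W)
  out <- data.frame(residue = names(p), p = unname(p),
                    class = contact_class(p), row.names = NULL)
  attr(out, "mean_simultaneous") <- mean_sim
  attr(out, "scheme") <- if (is.null(weights)) "uniform" else weights$scheme
  class(out) <- c("contact_table", "data.frame")
  out
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("contact_table (%s weights): mean simultaneous contacts %.2f\n",
              attr(x, "scheme"), attr(x, "mean_simultaneous")))
  print.data.frame(x, ...)
  invisible(x)
}
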