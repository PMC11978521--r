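# Nucleus-to-spot assignment and a toy connected-component segmenter used
# only to exercise image-derived fixtures; real pipelines consume externally
# produced centroid CSVs.

#' Assign nuclei to capture areas
#'
#' A nucleus belongs to a spot when its center lies within the spot radius
#' (diameter / 2), boundary inclusive. If several spots cover a nucleus the
#' nearest center wins, ties broken by spot id order. Nuclei covered by no
#' spot are marked out-spot (NA) and retained.
#'
#' @param nuclei nucleus_set.
#' @param geometry spot_geometry.
#' @return list with `nuclei` (nucleus_set with `assigned_spot` filled) and
#'   `N_s` (named integer vector of nuclei per spot, all spots present).
#' @export
assign_nuclei_to_spots <- function(nuclei, geometry) {
  if (length(geometry$spot_ids) == 0) stop("empty spot geometry")
  r <- geometry$spot_diameter_px / 2
  cx <- geometry$centers[, "x"]; cy <- geometry$centers[, "y"]
  assigned <- rep(NA_character_, nrow(nuclei))
  if (nrow(nuclei) > 0) {
    for (i in seq_len(nrow(nuclei))) {
      d2 <- (nuclei$x[i] - cx)^2 + (nuclei$y[i] - cy)^2
      ok <- which(d2 <= r^2 + 1e-9)
      if (length(ok) > 0) {
        best <- ok[order(d2[ok], geometry$spot_ids[ok])][1]
        assigned[i] <- geometry$spot_ids[best]
      }
    }
  }
  nuclei$assigned_spot <- assigned
  counts <- table(factor(assigned, levels = geometry$spot_ids))
  N_s <- stats::setNames(as.integer(counts), geometry$spot_ids)
  list(nuclei = nuclei, N_s = N_s)
}

#' Toy threshold-and-label nucleus segmenter
#'
#' Fixture plumbing only: thresholds a grayscale intensity matrix, labels
#' 8-connected components, drops components smaller than `min_area`, and
#' returns component centroids as nuclei. Coordinates follow the package
#' convention x = column, y = row.
#'
#' @param img 2-D numeric matrix of intensities.
#' @param threshold intensity threshold; pixels strictly above are
#'   foreground.
#' @param min_area minimum component pixel count.
#' @return nucleus_set of centroids.
#' @export
toy_segment <- function(img, threshold = 0.5, min_area = 4) {
  if (!is.matrix(img)) stop("toy_segment expects a 2-D matrix")
  fg <- img > threshold
  lab <- matrix(0L, nrow(img), ncol(img))
  nr <- nrow(img); nc <- ncol(img)
  nlab <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(fg)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pr <- ((p - 1) %% nr) + 1
      pc <- ((p - 1) %/% nr) + 1
      nbr_r <- pr + offs$dr
      nbr_c <- pc + offs$dc
      keep <- nbr_r >= 1 & nbr_r <= nr & nbr_c >= 1 & nbr_c <= nc
      idx <- (nbr_c[keep] - 1) * nr + nbr_r[keep]
      idx <- idx[fg[idx] & lab[idx] == 0L]
      if (length(idx) > 0) {
        lab[idx] <- nlab
        queue <- c(queue, idx)
      }
    }
  }
  if (nlab == 0L)
    return(nucleus_set(character(0), matrix(numeric(0), 0, 2)))
  rows <- ((which(lab > 0) - 1) %% nr) + 1
  cols <- ((which(lab > 0) - 1) %/% nr) + 1
  ids <- lab[lab > 0]
  area <- tabulate(ids, nbins = nlab)
  cy <- tapply(rows, ids, mean)
  cx <- tapply(cols, ids, mean)
  keep <- which(area >= min_area)
  nucleus_set(sprintf("nucleus_%d", seq_along(keep)),
              cbind(cx[keep], cy[keep]))
}
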