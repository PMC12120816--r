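spine_classes <- c("branched", "filopodia", "mushroom", "stubby", "thin",
                   "long_thin")

#' Classify dendritic spines by geometry
#'
#' Rule-based six-class morphometric classifier. The six defining
#' inequalities (filopodia: length > 2 um; long-thin: length < 2 um; thin:
#' length < 1 um; stubby: length:width ratio < 1; mushroom: width > 0.6 um;
#' branched: 2 or more heads) overlap, so a fixed decision sequence is
#' applied, first match wins:
#' heads >= 2 -> branched; length > 2 -> filopodia; width > 0.6 -> mushroom;
#' length/width < 1 -> stubby; length < 1 -> thin; otherwise long_thin.
#'
#' @param length_um spine length(s), micrometres (> 0).
#' @param width_um spine head width(s), micrometres (> 0).
#' @param heads number of heads (integer >= 1, default 1).
#' @return character vector of class labels; vectorized over inputs.
#' @export
classify_spine <- function(length_um, width_um, heads = 1L) {
  n <- max(length(length_um), length(width_um), length(heads))
  length_um <- rep_len(as.numeric(length_um), n)
  width_um <- rep_len(as.numeric(width_um), n)
  heads <- rep_len(as.integer(heads), n)
  if (any(length_um <= 0 | width_um <= 0)) stop("geometry must be positive")
  if (any(heads < 1L)) stop("heads must be >= 1")
  cls <- rep(NA_character_, n)
  cls[is.na(cls) & heads >= 2L] <- "branched"
  cls[is.na(cls) & length_um > 2] <- "filopodia"
  cls[is.na(cls) & width_um > 0.6] <- "mushroom"
  cls[is.na(cls) & length_um / width_um < 1] <- "stubby"
  cls[is.na(cls) & length_um < 1] <- "thin"
  cls[is.na(cls)] <- "long_thin"
  cls
}

#' Spine density and class composition of a dendrite segment
#'
#' @param spines data.frame with at least \code{length_um}, \code{width_um}
#'   and optionally \code{heads}; classes are assigned with
#'   \code{\link{classify_spine}} unless a \code{class} column is present.
#' @param segment_length_um analyzed segment length, micrometres (> 0;
#'   segments are typically ~50 um).
#' @param per_um normalization length (default 50: spines per 50 um).
#' @return list with \code{density_per_norm} (spines per \code{per_um} um),
#'   \code{n_spines}, \code{composition} (named proportions over the six
#'   classes, summing to 1; all-NA when the segment is empty and
#'   \code{empty = TRUE}).
#' @export
spine_density <- function(spines, segment_length_um, per_um = 50) {
  if (segment_length_um <= 0) stop("segment_length_um must be positive")
  n <- nrow(spines)
  if (n == 0) {
    comp <- stats::setNames(rep(NA_real_, length(spine_classes)),
                            spine_classes)
    return(list(density_per_norm = 0, n_spines = 0L, composition = comp,
                empty = TRUE))
  }
  cls <- if ("class" %in% names(spines)) spines$class
         else classify_spine(spines$length_um, spines$width_um,
                             if ("heads" %in% names(spines)) spines$heads
                             else 1L)
  comp <- table(factor(cls, levels = spine_classes)) / n
  list(density_per_norm = n * per_um / segment_length_um,
       n_spines = n,
       composition = stats::setNames(as.numeric(comp), spine_classes),
       empty = FALSE)
}

#' Hierarchical aggregation: segments to neurons to animals
#'
#' Mean of segment values per neuron, then mean of neuron values per animal
#' (unweighted at both levels, so neurons with two vs three segments carry
#' equal weight). The per-animal mean is the unit of analysis for group
#' comparisons.
#'
#' @param df data.frame with columns \code{animal}, \code{neuron},
#'   \code{value} (one row per segment).
#' @return data.frame with \code{animal}, \code{mean_value}, \code{n_neurons}.
#' @export
aggregate_hierarchy <- function(df) {
  need <- c("animal", "neuron", "value")
  if (!all(need %in% names(df))) stop("need columns animal, neuron, value")
  if (!nrow(df)) stop("empty hierarchy table")
  per_neuron <- stats::aggregate(value ~ animal + neuron, data = df, FUN = mean)
  per_animal <- stats::aggregate(value ~ animal, data = per_neuron, FUN = mean)
  nn <- stats::aggregate(neuron ~ animal, data = per_neuron,
                         FUN = function(x) length(unique(x)))
  out <- merge(per_animal, nn, by = "animal")
  names(out) <- c("animal", "mean_value", "n_neurons")
  out[order(out$animal), , drop = FALSE]
}

# even-odd (ray casting) point-in-polygon test, vectorized over points
points_in_polygon <- function(px, py, vx, vy) {
  nv <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}

# pixel mask of a polygon ROI: pixel centers at (col - 0.5, row - 0.5) in
# 0-based x/y-down pixel coordinates
roi_mask <- function(image, roi_xy) {
  nr <- nrow(image); nc <- ncol(image)
  px <- rep(seq_len(nc) - 0.5, each = nr)
  py <- rep(seq_len(nr) - 0.5, times = nc)
  matrix(points_in_polygon(px, py, roi_xy$x, roi_xy$y), nrow = nr)
}

#' Mean ROI intensity per square micrometre
#'
#' Sum of pixel intensities inside a polygonal ROI divided by the ROI area
#' in um^2 (pixel count times the pixel area). Pixels belong to the ROI when
#' their centers fall inside the polygon (even-odd rule). Polygon
#' coordinates are 0-based pixel coordinates, x right / y down.
#'
#' @param image numeric matrix (row = y, col = x).
#' @param roi_xy data.frame or list with \code{x}, \code{y} polygon vertices
#'   in pixel coordinates.
#' @param px_size_um pixel size, micrometres per pixel (> 0).
#' @return intensity per um^2 (scalar).
#' @export
roi_mean_intensity <- function(image, roi_xy, px_size_um) {
  if (px_size_um <= 0) stop("px_size_um must be positive")
  if (length(roi_xy$x) < 3L) stop("polygon needs at least 3 vertices")
  if (min(roi_xy$x) < 0 || max(roi_xy$x) > ncol(image) ||
      min(roi_xy$y) < 0 || max(roi_xy$y) > nrow(image))
    stop("ROI outside image bounds")
  mask <- roi_mask(image, roi_xy)
  npx <- sum(mask)
  if (npx == 0) stop("empty ROI: no pixel centers inside the polygon")
  sum(image[mask]) / (npx * px_size_um^2)
}

# connected-component labeling (8-connectivity) of a logical matrix by
# iterative flood fill; returns an integer label matrix (0 = background)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask & lab == 0L)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

#' Detect fluorescent puncta in one channel
#'
#' Global intensity threshold, 8-connected component labeling, and an area
#' band filter. Centroids are intensity-weighted and reported in
#' micrometres (x right, y down, origin at the image corner).
#'
#' @param image numeric intensity matrix (row = y).
#' @param intensity_threshold pixels strictly above this value are
#'   foreground.
#' @param min_area_um2,max_area_um2 area band in um^2 (components outside it
#'   are discarded).
#' @param px_size_um pixel size in micrometres.
#' @return data.frame of class \code{puncta_set}: \code{x_um}, \code{y_um},
#'   \code{area_um2}, \code{mean_intensity}.
#' @export
detect_puncta <- function(image, intensity_threshold, min_area_um2 = 0,
                          max_area_um2 = Inf, px_size_um = 1) {
  mask <- image > intensity_threshold
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0))
  class(empty) <- c("puncta_set", "data.frame")
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  px_area <- px_size_um^2
  nr <- nrow(image)
  out <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k)
    area <- length(idx) * px_area
    if (area < min_area_um2 || area > max_area_um2) return(NULL)
    wts <- image[idx]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    data.frame(x_um = sum((cols - 0.5) * wts) / sum(wts) * px_size_um,
               y_um = sum((rows - 0.5) * wts) / sum(wts) * px_size_um,
               area_um2 = area, mean_intensity = mean(wts))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  class(out) <- c("puncta_set", "data.frame")
  out
}

#' Colocalize two puncta sets
#'
#' Greedy nearest-neighbor matching: candidate pairs within
#' \code{max_dist_um} are accepted in order of increasing distance, each
#' punctum used at most once. The matched count is symmetric in the two
#' sets. The double-positive count is normalized to a 50 um dendritic
#' segment.
#'
#' @param a,b \code{puncta_set} data.frames (or any with \code{x_um},
#'   \code{y_um}).
#' @param max_dist_um matching radius (default 0.5).
#' @param segment_length_um length of the analyzed segment (default 50).
#' @param per_um normalization length (default 50).
#' @return list with \code{n_matched}, \code{double_positive_per_norm},
#'   \code{pairs} (data.frame of matched indices and distances).
#' @export
colocalize <- function(a, b, max_dist_um = 0.5, segment_length_um = 50,
                       per_um = 50) {
  if (segment_length_um <= 0) stop("segment_length_um must be positive")
  na <- nrow(a); nb <- nrow(b)
  pairs <- data.frame(i_a = integer(0), i_b = integer(0), dist_um = numeric(0))
  if (na > 0 && nb > 0) {
    d <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
    cand <- which(d <= max_dist_um, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_a <- logical(na); used_b <- logical(nb)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE; used_b[j] <- TRUE
          pairs <- rbind(pairs, data.frame(i_a = i, i_b = j,
                                           dist_um = d[i, j]))
        }
      }
    }
  }
  n <- nrow(pairs)
  list(n_matched = n,
       double_positive_per_norm = n * per_um / segment_length_um,
       pairs = pairs)
}
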