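#' Construct a worm image
#'
#' Light container for a 2-D grayscale image plus its physical pixel size,
#' the two pieces of information every length measurement needs.
#'
#' @param pixels Numeric matrix (rows x cols) of intensities.
#' @param px_size_um Pixel size in micrometres per pixel (> 0).
#' @return An object of class `worm_image`.
#' @export
worm_image <- function(pixels, px_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (nrow(pixels) < 3 || ncol(pixels) < 3) {
    abort("Image must be at least 3x3 pixels.")
  }
  assert_scalar_num(px_size_um, "px_size_um", positive = TRUE)
  structure(list(pixels = pixels, px_size_um = px_size_um),
            class = "worm_image")
}

#' @export
print.worm_image <- function(x, ...) {
  cat(sprintf("<worm_image> %d x %d px, %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$px_size_um))
  invisible(x)
}

# Otsu's criterion: threshold minimizing intraclass intensity variance.
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  brks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, brks, rightmost.closed = TRUE), n_bins)
  mids <- (brks[-1] + brks[-length(brks)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  tot_w <- w[n_bins]
  tot_m <- m[n_bins]
  w1 <- w[-n_bins]
  w2 <- tot_w - w1
  ok <- w1 > 0 & w2 > 0
  mu1 <- m[-n_bins] / w1
  mu2 <- (tot_m - m[-n_bins]) / w2
  between <- w1 * w2 * (mu1 - mu2)^2
  between[!ok] <- -Inf
  brks[which.max(between) + 1L]
}

#' Segment a worm from the background by intensity thresholding
#'
#' The default automatic threshold minimizes the intraclass intensity
#' variance over the grayscale histogram (Otsu's criterion). Foreground
#' polarity (bright worm on dark background or the reverse) is auto-detected
#' as the minority class unless forced.
#'
#' @param image A [worm_image()].
#' @param method `"auto_threshold"` (Otsu) or `"fixed"`.
#' @param fixed_threshold Threshold value when `method = "fixed"`.
#' @param polarity `"auto"`, `"bright"` or `"dark"` (the worm's intensity
#'   relative to background).
#' @return A logical matrix (the binary mask) with attribute
#'   `threshold`; errors if no foreground pixel survives, and warns when a
#'   forced polarity leaves the majority of pixels in the foreground.
#' @export
segment_worm <- function(image,
                         method = c("auto_threshold", "fixed"),
                         fixed_threshold = NULL,
                         polarity = c("auto", "bright", "dark")) {
  stopifnot(inherits(image, "worm_image"))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  px <- image$pixels
  thr <- switch(method,
    auto_threshold = otsu_threshold(as.vector(px)),
    fixed = {
      if (is.null(fixed_threshold)) abort("`fixed_threshold` is required.")
      fixed_threshold
    }
  )
  bright <- px > thr
  mask <- switch(polarity,
    bright = bright,
    dark = !bright,
    auto = if (mean(bright) <= 0.5) bright else !bright
  )
  if (!any(mask)) abort("no object found: segmentation left an empty mask")
  if (mean(mask) > 0.5) {
    warn("Foreground covers > 50% of pixels; likely polarity error.")
  }
  attr(mask, "threshold") <- thr
  mask
}

# linear (column-major) indices of the 8-neighbourhood graph of a mask
mask_edges <- function(mask, diagonals = TRUE) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  pair <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    from <- idx[ok]
    to <- from + dr + dc * nr
    keep <- mask[to]
    cbind(from[keep], to[keep])
  }
  dirs <- list(c(0L, 1L), c(1L, 0L))
  if (diagonals) dirs <- c(dirs, list(c(1L, 1L), c(-1L, 1L)))
  do.call(rbind, lapply(dirs, function(d) pair(d[1], d[2])))
}

# connected components over foreground pixels; returns list(membership
# (named by linear index), sizes)
mask_components <- function(mask) {
  idx <- which(mask)
  e <- mask_edges(mask, diagonals = TRUE)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(e[, 1]), to = as.character(e[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx))
  )
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(idx)]
  list(idx = idx, membership = as.integer(membership),
       sizes = as.integer(comp$csize))
}

#' Keep only the largest connected component of a mask
#'
#' Removes debris by retaining the largest 8-connected foreground
#' component. Ties are broken by scan order (column-major first pixel).
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return The filtered mask, with attribute `qc_multiple_components` set to
#'   `TRUE` when more than one component exceeds 5% of the largest's area.
#' @export
largest_component <- function(mask) {
  if (!any(mask)) abort("empty mask")
  cc <- mask_components(mask)
  max_size <- max(cc$sizes)
  big <- which(cc$sizes == max_size)
  # scan-order tie-break: component whose first pixel comes first
  keep_comp <- big[which.min(vapply(big, function(k) {
    min(cc$idx[cc$membership == k])
  }, numeric(1)))]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[cc$idx[cc$membership == keep_comp]] <- TRUE
  n_big <- sum(cc$sizes >= 0.05 * max_size)
  attr(out, "qc_multiple_components") <- n_big > 1L
  out
}

# shift a logical matrix, padding with FALSE
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

binary_erode3 <- function(m) {
  m & shift_mat(m, 1, 0) & shift_mat(m, -1, 0) &
    shift_mat(m, 0, 1) & shift_mat(m, 0, -1)
}

binary_dilate3 <- function(m) {
  m | shift_mat(m, 1, 0) | shift_mat(m, -1, 0) |
    shift_mat(m, 0, 1) | shift_mat(m, 0, -1)
}

# morphological opening with a 3x3 cross; smooths 1-px boundary noise
binary_open3 <- function(m) binary_dilate3(binary_erode3(m))

#' Skeletonize a binary mask by topology-preserving thinning
#'
#' Zhang-Suen iterative thinning: boundary pixels are peeled in two
#' alternating sub-iterations while preserving connectivity and endpoints,
#' converging to a one-pixel-wide, 8-connected medial skeleton.
#'
#' @param mask Logical matrix (one nonempty component).
#' @return Logical skeleton matrix. Errors if the mask vanishes under a
#'   3x3 opening (object thinner than one pixel).
#' @export
skeletonize <- function(mask) {
  if (!any(mask)) abort("empty mask")
  if (!any(binary_open3(mask)) && sum(mask) > 2) {
    abort("degenerate skeleton: mask thinner than 1 px after opening")
  }
  m <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift_mat(m, 1, 0)   # north neighbour value at each pixel
      p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1)
      p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0)
      p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1)
      p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# weighted 8-neighbour graph over skeleton pixels; weights 1 / sqrt(2)
skeleton_graph <- function(skel) {
  nr <- nrow(skel)
  e <- mask_edges(skel, diagonals = TRUE)
  idx <- which(skel)
  if (nrow(e) == 0) {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    igraph::V(g)$name <- as.character(idx)
    return(g)
  }
  dr <- abs(((e[, 1] - 1) %% nr) - ((e[, 2] - 1) %% nr))
  dc <- abs(((e[, 1] - 1) %/% nr) - ((e[, 2] - 1) %/% nr))
  w <- ifelse(dr + dc == 2, sqrt(2), 1)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(e[, 1]), to = as.character(e[, 2]),
                   weight = w),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx))
  )
  g
}

#' Extract the longest geodesic path through a skeleton
#'
#' Two-pass farthest-point search: from an arbitrary skeleton pixel find the
#' geodesically farthest pixel, then from there the farthest again; the
#' geodesic between the two final pixels is the skeleton's longest path.
#' Side branches (spurs) fall off the path, which makes the subsequent
#' length measurement parameter-free. Distances use the chamfer (1, sqrt 2)
#' metric on the 8-neighbour graph.
#'
#' @param skel Logical skeleton matrix.
#' @param px_size_um Pixel size carried into the returned path.
#' @return A `skeleton_path`: tibble with columns `row`, `col` (ordered,
#'   consecutive pixels 8-adjacent) and attributes `px_size_um`,
#'   `qc_disconnected_skeleton`, `qc_self_overlap_suspected`.
#' @export
longest_path <- function(skel, px_size_um = 1) {
  if (!any(skel)) abort("empty skeleton")
  nr <- nrow(skel)
  cc <- mask_components(skel)
  disconnected <- max(cc$membership) > 1L
  if (disconnected) {
    keep <- which.max(cc$sizes)
    skel2 <- matrix(FALSE, nr, ncol(skel))
    skel2[cc$idx[cc$membership == keep]] <- TRUE
    skel <- skel2
  }
  g <- skeleton_graph(skel)
  # cycle check on a reduced graph that drops diagonal shortcuts across
  # orthogonally-connected corners, so corners do not register as cycles
  self_overlap <- has_skeleton_cycle(skel)
  vnames <- igraph::V(g)$name
  if (length(vnames) == 1L) {
    idx <- as.integer(vnames)
    path <- tibble::tibble(row = ((idx - 1L) %% nr) + 1L,
                           col = ((idx - 1L) %/% nr) + 1L)
  } else {
    d0 <- igraph::distances(g, v = 1)
    a <- which.max(d0)
    d1 <- igraph::distances(g, v = a)
    b <- which.max(d1)
    vp <- igraph::shortest_paths(g, from = a, to = b,
                                 output = "vpath")$vpath[[1]]
    idx <- as.integer(igraph::V(g)$name[as.integer(vp)])
    path <- tibble::tibble(row = ((idx - 1L) %% nr) + 1L,
                           col = ((idx - 1L) %/% nr) + 1L)
  }
  structure(path,
            px_size_um = px_size_um,
            qc_disconnected_skeleton = disconnected,
            qc_self_overlap_suspected = self_overlap,
            class = c("skeleton_path", class(path)))
}

# cycle detection on the skeleton treated as a graph without corner-cutting
# diagonals: a cycle then indicates a genuinely closed (coiled) shape
has_skeleton_cycle <- function(skel) {
  nr <- nrow(skel)
  e <- mask_edges(skel, diagonals = TRUE)
  if (nrow(e) == 0) return(FALSE)
  dr <- ((e[, 2] - 1) %% nr) - ((e[, 1] - 1) %% nr)
  dc <- ((e[, 2] - 1) %/% nr) - ((e[, 1] - 1) %/% nr)
  diag <- abs(dr) + abs(dc) == 2
  # a diagonal edge is redundant if either shared orthogonal neighbour is set
  n1 <- e[, 1] + dr          # vertical step from 'from'
  n2 <- e[, 1] + dc * nr     # horizontal step from 'from'
  redundant <- diag & (skel[pmin(pmax(n1, 1), length(skel))] |
                         skel[pmin(pmax(n2, 1), length(skel))])
  e2 <- e[!redundant, , drop = FALSE]
  n_vert <- sum(skel)
  comp <- mask_components(skel)
  n_comp <- max(comp$membership)
  nrow(e2) > n_vert - n_comp
}

#' Chamfer length of an ordered pixel path
#'
#' Sums `px_size_um` per orthogonal step and `sqrt(2) * px_size_um` per
#' diagonal step between consecutive path pixels.
#'
#' @param path A `skeleton_path` or data frame with `row`, `col`.
#' @param px_size_um Pixel size; defaults to the path's own attribute.
#' @return Length in micrometres (0 for a single-pixel path).
#' @export
path_length <- function(path, px_size_um = NULL) {
  px_size_um <- px_size_um %||% attr(path, "px_size_um") %||% 1
  if (nrow(path) < 1) abort("path must contain at least one pixel")
  if (nrow(path) == 1) return(0)
  dr <- abs(diff(path$row))
  dc <- abs(diff(path$col))
  if (any(dr > 1 | dc > 1)) abort("path pixels must be 8-adjacent")
  sum(ifelse(dr + dc == 2, sqrt(2), 1)) * px_size_um
}

# Arc length of a smoothing spline through the path, parameterized by
# cumulative chamfer distance. Removes the orientation-dependent zigzag of
# the digital path; returns length in pixels.
spline_path_length <- function(path) {
  n <- nrow(path)
  if (n < 8) {
    dr <- abs(diff(path$row))
    dc <- abs(diff(path$col))
    return(sum(ifelse(dr + dc == 2, sqrt(2), 1)))
  }
  step <- ifelse(abs(diff(path$row)) + abs(diff(path$col)) == 2, sqrt(2), 1)
  s <- c(0, cumsum(step))
  df <- max(4, min(n - 2, round(n / 6)))
  fr <- stats::smooth.spline(s, path$row, df = df)
  fc <- stats::smooth.spline(s, path$col, df = df)
  grid <- seq(0, max(s), length.out = 8 * n)
  rr <- predict(fr, grid)$y
  cc <- predict(fc, grid)$y
  sum(sqrt(diff(rr)^2 + diff(cc)^2))
}

# end tangent of a path from a linear fit to the last k pixels
end_tangent <- function(path, k = 7, from_end = TRUE) {
  n <- nrow(path)
  k <- min(k, n)
  idx <- if (from_end) (n - k + 1):n else k:1
  t <- seq_len(k)
  v <- c(coef(lm(path$row[idx] ~ t))[2], coef(lm(path$col[idx] ~ t))[2])
  nv <- sqrt(sum(v^2))
  if (nv == 0) c(0, 0) else v / nv
}

# distance (px) from a path endpoint to the mask boundary along the tangent
tip_extension <- function(mask, start_rc, tangent, max_steps = 200) {
  if (all(tangent == 0)) return(0)
  step <- 0.25
  d <- 0
  for (i in seq_len(max_steps)) {
    d2 <- d + step
    r <- round(start_rc[1] + tangent[1] * d2)
    c <- round(start_rc[2] + tangent[2] * d2)
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask) || !mask[r, c]) {
      break
    }
    d <- d2
  }
  d
}

#' Measure worm body length from a grayscale image
#'
#' Full morphometry chain: threshold segmentation, debris removal (largest
#' 8-connected component), optional 3x3 opening to smooth segmentation
#' noise, topology-preserving thinning to a medial skeleton, and longest
#' geodesic path extraction. By default the path is then smoothed with a
#' spline (removing the orientation-dependent zigzag bias of a digital
#' path) and extended at both tips to the mask boundary minus the estimated
#' cap radius, compensating the end retraction of iterative thinning: the
#' medial axis of a tube of radius r runs the full centerline, ending r
#' inside the rounded caps. With `smooth_path = FALSE, extend_tips = FALSE`
#' the result is the bit-exact chamfer (1, sqrt 2) length of the raw path.
#' Quality-control flags from every stage are propagated.
#'
#' @param image A [worm_image()].
#' @param method,fixed_threshold,polarity Passed to [segment_worm()].
#' @param smooth_mask Apply a 3x3 binary opening before thinning
#'   (default `TRUE`).
#' @param smooth_path Spline-smooth the longest path (default `TRUE`).
#' @param extend_tips Compensate thinning end retraction (default `TRUE`).
#' @return A one-row tibble: `length_um`, `n_foreground_px`,
#'   `qc_multiple_components`, `qc_touching_border`,
#'   `qc_self_overlap_suspected`.
#' @export
#' @examples
#' w <- gen_worm_image(210, amplitude_um = 0, noise_sd = 0, seed = 1)
#' measure_worm_length(w$image)
measure_worm_length <- function(image,
                                method = c("auto_threshold", "fixed"),
                                fixed_threshold = NULL,
                                polarity = c("auto", "bright", "dark"),
                                smooth_mask = TRUE,
                                smooth_path = TRUE,
                                extend_tips = TRUE) {
  stopifnot(inherits(image, "worm_image"))
  mask <- segment_worm(image, method = method,
                       fixed_threshold = fixed_threshold, polarity = polarity)
  mask <- largest_component(mask)
  multi <- isTRUE(attr(mask, "qc_multiple_components"))
  touching <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  work <- if (smooth_mask) {
    op <- binary_open3(mask)
    if (any(op)) largest_component(op) else mask
  } else {
    mask
  }
  skel <- skeletonize(work)
  path <- longest_path(skel, px_size_um = image$px_size_um)

  len_px <- if (smooth_path) spline_path_length(path)
            else path_length(path, px_size_um = 1)

  if (extend_tips && nrow(path) >= 8) {
    # cap radius from the area relation area = 2 r L + pi r^2
    area <- sum(work)
    l0 <- max(len_px, 1)
    r_hat <- (-2 * l0 + sqrt(4 * l0^2 + 4 * pi * area)) / (2 * pi)
    ext_head <- tip_extension(work, c(path$row[1], path$col[1]),
                              end_tangent(path, from_end = FALSE))
    ext_tail <- tip_extension(work, c(path$row[nrow(path)],
                                      path$col[nrow(path)]),
                              end_tangent(path, from_end = TRUE))
    len_px <- len_px + max(0, ext_head - r_hat) + max(0, ext_tail - r_hat)
  }

  tibble::tibble(
    length_um = len_px * image$px_size_um,
    n_foreground_px = sum(mask),
    qc_multiple_components = multi,
    qc_touching_border = touching,
    qc_self_overlap_suspected = isTRUE(attr(path, "qc_self_overlap_suspected"))
  )
}

#' Measure a batch of worm images
#'
#' @param images A list of [worm_image()] objects or a tibble with a list
#'   column `image` (as produced by [gen_worm_batch()]).
#' @param ... Passed to [measure_worm_length()].
#' @return A tibble with one row per image (id column preserved if present).
#' @export
measure_worm_batch <- function(images, ...) {
  if (is.data.frame(images)) {
    res <- dplyr::bind_rows(purrr::map(images$image, measure_worm_length, ...))
    dplyr::bind_cols(images[, setdiff(names(images), "image"), drop = FALSE],
                     res)
  } else {
    dplyr::bind_rows(purrr::map(images, measure_worm_length, ...))
  }
}
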