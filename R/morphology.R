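# Binary morphology on logical matrices. Foreground = TRUE; pixels outside
# the frame are background. The named operators (close, thin, skel, diag,
# spur) follow the classical 3x3 lookup-table semantics of the standard image
# processing literature; components and skeletons use 8-connectivity
# throughout.

# 8-neighbourhood, Zhang-Suen ordering: P2 = N, P3 = NE, P4 = E, P5 = SE,
# P6 = S, P7 = SW, P8 = W, P9 = NW. Row index grows downward (south).
neighbours8 <- function(m) {
  list(
    p2 = shift_mat(m, 1, 0, pad = "zero"),    # value of the pixel to the north
    p3 = shift_mat(m, 1, -1, pad = "zero"),
    p4 = shift_mat(m, 0, -1, pad = "zero"),
    p5 = shift_mat(m, -1, -1, pad = "zero"),
    p6 = shift_mat(m, -1, 0, pad = "zero"),
    p7 = shift_mat(m, -1, 1, pad = "zero"),
    p8 = shift_mat(m, 0, 1, pad = "zero"),
    p9 = shift_mat(m, 1, 1, pad = "zero")
  )
}

#' Binary dilation and erosion with a 3 x 3 square element
#'
#' Elementary building blocks of the ridge clean-up. Pixels outside the frame
#' are treated as background.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same shape.
#' @export
bw_dilate <- function(mask) {
  n <- neighbours8(mask)
  mask | n$p2 | n$p3 | n$p4 | n$p5 | n$p6 | n$p7 | n$p8 | n$p9
}

#' @rdname bw_dilate
#' @export
bw_erode <- function(mask) {
  n <- neighbours8(mask)
  mask & n$p2 & n$p3 & n$p4 & n$p5 & n$p6 & n$p7 & n$p8 & n$p9
}

# Iterate a mask -> mask operator until the image no longer changes, capped.
iterate_until_stable <- function(mask, f, max_iter = 100L) {
  for (i in seq_len(max_iter)) {
    nxt <- f(mask)
    if (identical(nxt, mask)) return(mask)
    mask <- nxt
  }
  warning("morphological iteration did not converge within ", max_iter, " passes")
  mask
}

#' Morphological closing (dilation followed by erosion)
#'
#' Bridges 1-px gaps between nearby structures. `n_iter = Inf` (default)
#' repeats the close until the image is stable (closing is idempotent, so
#' this normally terminates after one extra pass).
#'
#' @param mask logical matrix.
#' @param n_iter number of passes or `Inf` for until-stable.
#' @return Logical matrix.
#' @export
bw_close <- function(mask, n_iter = Inf) {
  f <- function(m) bw_erode(bw_dilate(m))
  if (is.infinite(n_iter)) iterate_until_stable(mask, f)
  else { for (i in seq_len(n_iter)) mask <- f(mask); mask }
}

# Number of 0->1 transitions around the circular neighbour sequence
# P2, P3, ..., P9, P2 (the crossing number A of Zhang-Suen).
crossing_number <- function(n) {
  (!n$p2 & n$p3) + (!n$p3 & n$p4) + (!n$p4 & n$p5) + (!n$p5 & n$p6) +
  (!n$p6 & n$p7) + (!n$p7 & n$p8) + (!n$p8 & n$p9) + (!n$p9 & n$p2)
}

neighbour_count <- function(n) {
  n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
}

#' Morphological thinning
#'
#' Two-subiteration thinning (Guo-Hall) that reduces blobs to 8-connected,
#' 1-px-wide lines while preserving connectivity and endpoints. `n_iter = Inf`
#' iterates to convergence.
#'
#' @param mask logical matrix.
#' @param n_iter number of full (two-subiteration) passes or `Inf`.
#' @return Logical matrix.
#' @export
bw_thin <- function(mask, n_iter = Inf) {
  subpass <- function(m, first) {
    n <- neighbours8(m)
    c1 <- (!n$p2 & (n$p3 | n$p4)) + (!n$p4 & (n$p5 | n$p6)) +
          (!n$p6 & (n$p7 | n$p8)) + (!n$p8 & (n$p9 | n$p2))
    n1 <- (n$p9 | n$p2) + (n$p3 | n$p4) + (n$p5 | n$p6) + (n$p7 | n$p8)
    n2 <- (n$p2 | n$p3) + (n$p4 | n$p5) + (n$p6 | n$p7) + (n$p8 | n$p9)
    nmin <- pmin(n1, n2)
    cond <- if (first) (n$p2 | n$p3 | !n$p5) & n$p4
            else       (n$p6 | n$p7 | !n$p9) & n$p8
    del <- m & (c1 == 1) & (nmin >= 2) & (nmin <= 3) & !cond
    m & !del
  }
  pass <- function(m) subpass(subpass(m, TRUE), FALSE)
  if (is.infinite(n_iter)) iterate_until_stable(mask, pass)
  else { for (i in seq_len(n_iter)) mask <- pass(mask); mask }
}

#' Morphological skeletonization
#'
#' Sequential border thinning that removes simple boundary pixels (crossing
#' number 1, between 2 and 6 neighbours) from the north, south, east and west
#' borders in turn, preserving connectivity and endpoints. Applied for a
#' fixed number of iterations (the portrait pipeline uses 4) or to
#' convergence with `n_iter = Inf`.
#'
#' @param mask logical matrix.
#' @param n_iter number of passes (default 4) or `Inf`.
#' @return Logical matrix.
#' @export
bw_skel <- function(mask, n_iter = 4L) {
  border_pass <- function(m, which_border) {
    n <- neighbours8(m)
    a <- crossing_number(n)
    b <- neighbour_count(n)
    border <- switch(which_border,
      n = !n$p2, s = !n$p6, e = !n$p4, w = !n$p8)
    del <- m & border & (a == 1) & (b >= 2) & (b <= 6)
    m & !del
  }
  pass <- function(m) {
    for (side in c("n", "s", "e", "w")) m <- border_pass(m, side)
    m
  }
  if (is.infinite(n_iter)) iterate_until_stable(mask, pass)
  else { for (i in seq_len(n_iter)) mask <- pass(mask); mask }
}

#' Diagonal fill
#'
#' Fills a background pixel when two of its 4-neighbours on adjacent sides
#' are foreground but the diagonal between them is background, turning
#' corner-to-corner (8-connected) links into 4-connected ones. Iterated to
#' convergence by default.
#'
#' @param mask logical matrix.
#' @param n_iter passes or `Inf`.
#' @return Logical matrix.
#' @export
bw_diag <- function(mask, n_iter = Inf) {
  pass <- function(m) {
    n <- neighbours8(m)
    fill <- !m & ((n$p2 & n$p4 & !n$p3) | (n$p4 & n$p6 & !n$p5) |
                  (n$p6 & n$p8 & !n$p7) | (n$p8 & n$p2 & !n$p9))
    m | fill
  }
  if (is.infinite(n_iter)) iterate_until_stable(mask, pass)
  else { for (i in seq_len(n_iter)) mask <- pass(mask); mask }
}

#' Spur removal
#'
#' Removes endpoint pixels (foreground pixels with exactly one foreground
#' 8-neighbour). A single pass (the default) removes 1-px spurs; note that
#' iterating to convergence would consume every open curve end-to-end, so the
#' portrait pipeline deliberately uses one pass.
#'
#' @param mask logical matrix.
#' @param n_iter passes (default 1) or `Inf`.
#' @return Logical matrix.
#' @export
bw_spur <- function(mask, n_iter = 1L) {
  pass <- function(m) {
    n <- neighbours8(m)
    m & !(neighbour_count(n) == 1)
  }
  if (is.infinite(n_iter)) iterate_until_stable(mask, pass)
  else { for (i in seq_len(n_iter)) mask <- pass(mask); mask }
}

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return List with `labels` (integer matrix, 0 = background) and `n`
#'   (number of components).
#' @export
label_components <- function(mask) {
  idx <- which(mask)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(list(labels = labels, n = 0L))
  H <- nrow(mask); W <- ncol(mask)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  pos <- integer(H * W)
  pos[idx] <- seq_along(idx)
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    rr <- r + d[1]; cc <- c + d[2]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    nb <- (cc[ok] - 1L) * H + rr[ok]
    hit <- pos[nb] > 0L
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit], pos[nb][hit]))
    }
  }
  g <- igraph::graph_from_edgelist(
    rbind(cbind(seq_along(idx), seq_along(idx)), edges), directed = FALSE)
  comp <- igraph::components(g)
  labels[idx] <- comp$membership[seq_along(idx)]
  list(labels = labels, n = as.integer(comp$no))
}
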