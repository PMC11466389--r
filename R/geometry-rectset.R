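#' Rectilinear planar geometry
#'
#' All geometry in this package is rectilinear: a polygon (or multipolygon)
#' is represented as a *rect set*, a union of axis-aligned rectangles in a
#' shared planar Cartesian coordinate system (unit: km in synthetic mode).
#' Boolean operations (union, intersection, difference) are computed exactly
#' by slab decomposition over the x breakpoints, so areas are conserved to
#' floating-point accuracy. This covers every shape the package constructs:
#' census blocks, tracts, counties and sewersheds are rectangles or unions
#' and differences of rectangles.
#'
#' A rect set is stored as a data frame with columns `xmin`, `ymin`,
#' `xmax`, `ymax`, one row per rectangle. The canonical (normalized) form
#' holds pairwise-disjoint rectangles; the empty set has zero rows.
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of rectangle bounds
#'   (recycled to a common length). Each rectangle must have strictly
#'   positive width and height.
#' @return `rect_set()` returns an object of class `rect_set`.
#' @examples
#' a <- rect_set(0, 0, 2, 1)
#' b <- rect_set(1, 0, 3, 1)
#' rs_area(rs_union(a, b))      # 3
#' rs_area(rs_intersect(a, b))  # 1
#' rs_area(rs_difference(a, b)) # 1
#' @export
rect_set <- function(xmin = numeric(), ymin = numeric(),
                     xmax = numeric(), ymax = numeric()) {
  n <- max(length(xmin), length(ymin), length(xmax), length(ymax))
  if (n > 0) {
    xmin <- rep_len(as.numeric(xmin), n)
    ymin <- rep_len(as.numeric(ymin), n)
    xmax <- rep_len(as.numeric(xmax), n)
    ymax <- rep_len(as.numeric(ymax), n)
  }
  r <- data.frame(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  if (nrow(r) > 0) {
    if (!all(is.finite(as.matrix(r)))) {
      abort_geometry("rect_set: bounds must be finite")
    }
    if (any(r$xmax <= r$xmin) || any(r$ymax <= r$ymin)) {
      abort_geometry("rect_set: rectangles must have positive width and height")
    }
  }
  class(r) <- c("rect_set", "data.frame")
  r
}

#' @rdname rect_set
#' @export
rs_empty <- function() rect_set()

#' @param r,a,b rect sets.
#' @rdname rect_set
#' @export
rs_is_empty <- function(r) nrow(r) == 0L

as_rect_set <- function(r) {
  if (inherits(r, "rect_set")) return(r)
  rect_set(r$xmin, r$ymin, r$xmax, r$ymax)
}

# Merge a set of 1-d intervals (matrix cols lo,hi) into disjoint sorted form;
# touching intervals are coalesced.
merge_intervals <- function(lo, hi) {
  if (length(lo) == 0L) return(cbind(lo = numeric(), hi = numeric()))
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  k <- 1L
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= out_hi[k]) {
      if (hi[i] > out_hi[k]) out_hi[k] <- hi[i]
    } else {
      k <- k + 1L
      out_lo[k] <- lo[i]; out_hi[k] <- hi[i]
    }
  }
  cbind(lo = out_lo, hi = out_hi)
}

# Set difference of merged interval unions: A \ B.
diff_intervals <- function(a, b) {
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  out_lo <- numeric(); out_hi <- numeric()
  for (i in seq_len(nrow(a))) {
    lo <- a[i, 1]; hi <- a[i, 2]
    cur <- lo
    for (j in seq_len(nrow(b))) {
      blo <- b[j, 1]; bhi <- b[j, 2]
      if (bhi <= cur || blo >= hi) next
      if (blo > cur) {
        out_lo <- c(out_lo, cur); out_hi <- c(out_hi, blo)
      }
      cur <- max(cur, bhi)
      if (cur >= hi) break
    }
    if (cur < hi) {
      out_lo <- c(out_lo, cur); out_hi <- c(out_hi, hi)
    }
  }
  cbind(lo = out_lo, hi = out_hi)
}

# Slab decomposition: returns list(xs = slab breakpoints, ints = list of
# merged y-interval matrices, one per slab).
rs_slabs <- function(r, xs = NULL) {
  if (is.null(xs)) xs <- sort(unique(c(r$xmin, r$xmax)))
  ints <- vector("list", max(length(xs) - 1L, 0L))
  for (j in seq_along(ints)) {
    sel <- r$xmin <= xs[j] & r$xmax >= xs[j + 1L]
    ints[[j]] <- merge_intervals(r$ymin[sel], r$ymax[sel])
  }
  list(xs = xs, ints = ints)
}

# Rebuild a canonical rect set from slabs, merging x-adjacent slabs whose
# y-structure is identical.
rs_from_slabs <- function(xs, ints) {
  xmin <- numeric(); ymin <- numeric(); xmax <- numeric(); ymax <- numeric()
  j <- 1L
  nslab <- length(ints)
  while (j <= nslab) {
    cur <- ints[[j]]
    k <- j
    while (k + 1L <= nslab && identical(ints[[k + 1L]], cur)) k <- k + 1L
    if (nrow(cur) > 0L) {
      xmin <- c(xmin, rep(xs[j], nrow(cur)))
      xmax <- c(xmax, rep(xs[k + 1L], nrow(cur)))
      ymin <- c(ymin, cur[, 1])
      ymax <- c(ymax, cur[, 2])
    }
    j <- k + 1L
  }
  rect_set(xmin, ymin, xmax, ymax)
}

#' @rdname rect_set
#' @export
rs_normalize <- function(r) {
  r <- as_rect_set(r)
  if (nrow(r) == 0L) return(r)
  s <- rs_slabs(r)
  rs_from_slabs(s$xs, s$ints)
}

#' @rdname rect_set
#' @export
rs_area <- function(r) {
  r <- rs_normalize(r)
  if (nrow(r) == 0L) return(0)
  sum((r$xmax - r$xmin) * (r$ymax - r$ymin))
}

#' @rdname rect_set
#' @export
rs_union <- function(a, b) {
  a <- as_rect_set(a); b <- as_rect_set(b)
  rs_normalize(rect_set(c(a$xmin, b$xmin), c(a$ymin, b$ymin),
                        c(a$xmax, b$xmax), c(a$ymax, b$ymax)))
}

#' @rdname rect_set
#' @export
rs_intersect <- function(a, b) {
  a <- as_rect_set(a); b <- as_rect_set(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(rs_empty())
  xmin <- numeric(); ymin <- numeric(); xmax <- numeric(); ymax <- numeric()
  for (i in seq_len(nrow(a))) {
    ix1 <- pmax(a$xmin[i], b$xmin); ix2 <- pmin(a$xmax[i], b$xmax)
    iy1 <- pmax(a$ymin[i], b$ymin); iy2 <- pmin(a$ymax[i], b$ymax)
    keep <- ix2 > ix1 & iy2 > iy1
    xmin <- c(xmin, ix1[keep]); xmax <- c(xmax, ix2[keep])
    ymin <- c(ymin, iy1[keep]); ymax <- c(ymax, iy2[keep])
  }
  rs_normalize(rect_set(xmin, ymin, xmax, ymax))
}

#' @rdname rect_set
#' @export
rs_difference <- function(a, b) {
  a <- as_rect_set(a); b <- as_rect_set(b)
  if (nrow(a) == 0L) return(rs_empty())
  if (nrow(b) == 0L) return(rs_normalize(a))
  xs <- sort(unique(c(a$xmin, a$xmax, b$xmin, b$xmax)))
  sa <- rs_slabs(a, xs)
  sb <- rs_slabs(b, xs)
  ints <- vector("list", length(xs) - 1L)
  for (j in seq_along(ints)) {
    ints[[j]] <- diff_intervals(sa$ints[[j]], sb$ints[[j]])
  }
  rs_from_slabs(xs, ints)
}

# Closed-set intersection test (TRUE also when boundaries merely touch).
rs_touches_or_overlaps <- function(a, b) {
  a <- as_rect_set(a); b <- as_rect_set(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
  for (i in seq_len(nrow(a))) {
    hit <- a$xmin[i] <= b$xmax & a$xmax >= b$xmin &
      a$ymin[i] <= b$ymax & a$ymax >= b$ymin
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Test points for membership in a rect set
#'
#' Membership uses closed rectangles, so points on a boundary are inside.
#'
#' @param px,py numeric coordinate vectors (same length).
#' @param r a rect set.
#' @return logical vector, one element per point.
#' @export
rs_contains_points <- function(px, py, r) {
  r <- as_rect_set(r)
  out <- rep(FALSE, length(px))
  for (i in seq_len(nrow(r))) {
    out <- out | (px >= r$xmin[i] & px <= r$xmax[i] &
                    py >= r$ymin[i] & py <= r$ymax[i])
  }
  out
}

#' @rdname rect_set
#' @export
rs_bbox <- function(r) {
  r <- as_rect_set(r)
  if (nrow(r) == 0L) return(c(xmin = NA_real_, ymin = NA_real_,
                              xmax = NA_real_, ymax = NA_real_))
  c(xmin = min(r$xmin), ymin = min(r$ymin),
    xmax = max(r$xmax), ymax = max(r$ymax))
}

# Vectorized area of intersection between many single-rectangle units and a
# normalized (disjoint) rect set: overlaps with disjoint rects simply add.
rect_overlap_area <- function(uxmin, uymin, uxmax, uymax, region_rs) {
  region_rs <- rs_normalize(region_rs)
  out <- numeric(length(uxmin))
  for (i in seq_len(nrow(region_rs))) {
    w <- pmin(uxmax, region_rs$xmax[i]) - pmax(uxmin, region_rs$xmin[i])
    h <- pmin(uymax, region_rs$ymax[i]) - pmax(uymin, region_rs$ymin[i])
    out <- out + pmax(w, 0) * pmax(h, 0)
  }
  out
}

#' @export
print.rect_set <- function(x, ...) {
  cat(sprintf("<rect_set: %d rectangle(s), area %.6g>\n", nrow(x), rs_area(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
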