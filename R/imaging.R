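# Nuclear segmentation, eroded-nucleus / cytoplasmic-ring compartment
# masks, per-cell intensity measurement and simple nearest-neighbor frame
# linking.  Images are plain numeric matrices (row = y, column = x;
# distances in pixels).  The normative mask geometry: nuclear masks eroded
# 2 px from the border, cytoplasmic ring restricted to within 5 px
# (Euclidean) of the nuclear border.

#' Otsu threshold of an intensity image
#'
#' @param img numeric matrix.
#' @param n_bins histogram bins.
#' @return threshold value maximizing between-class variance.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w0c <- w0[-n_bins]; muc <- mu[-n_bins]
  between <- (mu_t * w0c - muc)^2 / (w0c * (1 - w0c))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  (mids[k] + mids[k + 1L]) / 2
}

# 8-connected component labeling by BFS (queue over linear indices).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  fg <- which(mask)
  if (!length(fg)) return(lab)
  queue <- integer(length(fg))
  for (p0 in fg) {
    if (lab[p0] != 0L) next
    cur <- cur + 1L
    lab[p0] <- cur
    queue[1L] <- p0
    qh <- 1L; qt <- 1L
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; ccn <- cc + dc
        if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
        q <- rr + (ccn - 1L) * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          qt <- qt + 1L
          queue[qt] <- q
        }
      }
    }
  }
  lab
}

# Fill holes: background regions not connected to the image border become
# foreground.
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- !mask
  pad[1L, ] <- TRUE; pad[nr + 2L, ] <- TRUE
  pad[, 1L] <- TRUE; pad[, nc + 2L] <- TRUE
  labs <- label_components(pad)
  border_lab <- labs[1L, 1L]
  inner <- labs[2:(nr + 1L), 2:(nc + 1L)]
  mask | (inner != border_lab & inner != 0L)
}

# 1-D squared-distance transform (lower envelope of parabolas), tracking
# the argmin position.  f may contain Inf (no site).
fz1d <- function(f) {
  m <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) {
    return(list(d = rep(Inf, m), arg = rep(NA_integer_, m)))
  }
  v <- integer(length(fin)); z <- numeric(length(fin) + 1L)
  k <- 1L
  v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(fin) > 1L) {
    for (q in fin[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
        if (k > 1L && s <= z[k]) { k <- k - 1L } else break
      }
      k <- k + 1L
      v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  d <- numeric(m); arg <- integer(m); j <- 1L
  for (q in seq_len(m)) {
    while (z[j + 1L] < q) j <- j + 1L
    p <- v[j]
    d[q] <- (q - p)^2 + f[p]
    arg[q] <- p
  }
  list(d = d, arg = arg)
}

#' Exact Euclidean distance transform with feature (nearest-site) indices
#'
#' For every pixel, the Euclidean distance to the nearest `TRUE` pixel of
#' `sites` and the linear index of that pixel (ties resolved
#' deterministically by scan order).
#'
#' @param sites logical matrix.
#' @return list with numeric matrix `dist` and integer matrix `index`.
#' @export
distance_transform <- function(sites) {
  nr <- nrow(sites); nc <- ncol(sites)
  # pass 1: per-column nearest site row (vectorized across columns)
  f <- matrix(Inf, nr, nc)
  srow <- matrix(NA_integer_, nr, nc)
  dcur <- rep(Inf, nc); rcur <- rep(NA_integer_, nc)
  for (r in seq_len(nr)) {
    hit <- sites[r, ]
    dcur <- ifelse(hit, 0, dcur + 1)
    rcur[hit] <- r
    f[r, ] <- dcur
    srow[r, ] <- rcur
  }
  dcur <- rep(Inf, nc); rcur <- rep(NA_integer_, nc)
  for (r in rev(seq_len(nr))) {
    hit <- sites[r, ]
    dcur <- ifelse(hit, 0, dcur + 1)
    rcur[hit] <- r
    better <- dcur < f[r, ]
    f[r, better] <- dcur[better]
    srow[r, better] <- rcur[better]
  }
  f2 <- f^2
  d <- matrix(Inf, nr, nc)
  idx <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) {
    res <- fz1d(f2[r, ])
    d[r, ] <- res$d
    ok <- !is.na(res$arg)
    if (any(ok)) {
      cols <- res$arg[ok]
      idx[r, ok] <- srow[r + (cols - 1L) * nr] + (cols - 1L) * nr
    }
  }
  list(dist = sqrt(d), index = idx)
}

# Grayscale max filter by repeated 3x3 dilation (radius steps, Chebyshev
# window); used only for seed detection.
max_filter <- function(img, radius) {
  out <- img
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_len(radius)) {
    m <- out
    sh <- function(dr, dc) {
      res <- matrix(-Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      res[rs, cs] <- m[rs - dr, cs - dc]
      res
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- pmax(out, sh(dr, dc))
    }
  }
  out
}

#' Segment nuclei from a nuclear-marker image
#'
#' Default pipeline: Otsu threshold, hole filling, connected components,
#' and (optionally) splitting of touching nuclei by partitioning each
#' component among the local maxima of its Euclidean distance transform
#' (each foreground pixel goes to its nearest seed -- the distance-
#' transform watershed specialized to convex blobs).  Objects smaller
#' than `min_area` are removed and labels are renumbered consecutively.
#'
#' @param img single-channel numeric matrix, nonnegative intensities.
#' @param min_area minimum object area in pixels.
#' @param threshold_method `"otsu"` or a numeric threshold value.
#' @param split_touching split touching nuclei via distance-transform
#'   maxima.
#' @param min_distance minimum seed separation in pixels.
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(img, min_area = 20, threshold_method = "otsu",
                           split_touching = TRUE, min_distance = 5) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("segment_nuclei: input must be a 2-D numeric matrix")
  }
  thr <- if (is.numeric(threshold_method)) threshold_method
         else if (identical(threshold_method, "otsu")) otsu_threshold(img)
         else stop("segment_nuclei: unknown threshold_method")
  mask <- img > thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  mask <- fill_holes(mask)
  comp <- label_components(mask)
  lab <- comp
  if (split_touching) {
    dt <- distance_transform(!mask)$dist
    dt[!mask] <- 0
    mx <- max_filter(dt, max(1L, as.integer(min_distance)))
    seeds <- mask & dt >= mx - 1e-9 & dt >= 2
    if (any(seeds)) {
      seed_lab <- label_components(seeds)
      ft <- distance_transform(seeds)
      assigned <- matrix(0L, nrow(img), ncol(img))
      fgi <- which(mask)
      near <- ft$index[fgi]
      same_comp <- comp[near] == comp[fgi]
      assigned[fgi[same_comp]] <- seed_lab[near[same_comp]]
      # components without a seed (or cross-component assignments) keep
      # their connected-component identity
      left <- fgi[!same_comp | assigned[fgi] == 0L]
      if (length(left)) {
        assigned[left] <- max(seed_lab) + comp[left]
      }
      lab <- assigned
    }
  }
  # area filter + consecutive relabeling (ordered by first pixel)
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  if (!length(ids)) return(matrix(0L, nrow(img), ncol(img)))
  areas <- tabulate(lab[lab > 0L], max(ids))[ids]
  keep <- ids[areas >= min_area]
  out <- matrix(0L, nrow(img), ncol(img))
  if (length(keep)) {
    first_px <- vapply(keep, function(id) which(lab == id)[1L], 1L)
    keep <- keep[order(first_px)]
    for (i in seq_along(keep)) out[lab == keep[i]] <- i
  }
  out
}

#' Build eroded-nuclear and cytoplasmic-ring compartment masks
#'
#' The nuclear mask of each cell is its label eroded `erode_px` pixels
#' (3x3 structuring element applied `erode_px` times).  The cytoplasmic
#' ring is the set of non-nuclear pixels within `ring_px` (Euclidean) of
#' the nuclear border, with contested pixels assigned to the nearer
#' nucleus (exact ties resolved deterministically by scan order).  Cells
#' whose nucleus is annihilated by erosion, or whose ring is empty, are
#' flagged unmeasurable, never dropped silently.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param erode_px nuclear erosion in pixels (default 2).
#' @param ring_px ring width beyond the nuclear border in pixels
#'   (default 5).
#' @return object of class `compartment_masks`: list with `labels`
#'   (input), `nuclear` (eroded label matrix), `ring` (ring label
#'   matrix), the parameters, `cells` and `unmeasurable` id vectors.
#' @export
make_compartment_masks <- function(labels, erode_px = 2, ring_px = 5) {
  if (!is.matrix(labels)) stop("make_compartment_masks: labels must be a matrix")
  storage.mode(labels) <- "integer"
  nr <- nrow(labels); nc <- ncol(labels)
  er <- labels
  if (erode_px > 0) {
    for (k in seq_len(erode_px)) {
      keep <- er > 0L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        nb <- matrix(0L, nr, nc)
        rs <- max(1, 1 + dr):min(nr, nr + dr)
        cs <- max(1, 1 + dc):min(nc, nc + dc)
        nb[rs, cs] <- er[rs - dr, cs - dc]
        keep <- keep & nb == er
      }
      er[!keep] <- 0L
    }
  }
  ring <- matrix(0L, nr, nc)
  if (ring_px > 0 && any(labels > 0L)) {
    ft <- distance_transform(labels > 0L)
    sel <- labels == 0L & ft$dist > 0 & ft$dist <= ring_px + 1e-9
    ring[sel] <- labels[ft$index[sel]]
  }
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  nuc_n <- tabulate(er[er > 0L], if (length(ids)) max(ids) else 0L)
  ring_n <- tabulate(ring[ring > 0L], if (length(ids)) max(ids) else 0L)
  unmeas <- ids[nuc_n[ids] == 0L | ring_n[ids] == 0L]
  structure(list(labels = labels, nuclear = er, ring = ring,
                 erode_px = erode_px, ring_px = ring_px,
                 cells = ids, unmeasurable = unmeas),
            class = "compartment_masks")
}

#' Measure per-cell compartment intensities and C/N ratio
#'
#' Means of the reporter channel over each cell's eroded nuclear mask and
#' cytoplasmic ring, and their ratio C/N (cytoplasmic / nuclear).
#' Undefined ratios (empty compartment or nonpositive nuclear mean) are
#' flagged via `measurable = FALSE` with `cn = NA`.
#'
#' @param reporter numeric matrix, same dimensions as the masks.
#' @param masks a `compartment_masks` object.
#' @return data.frame with one row per cell: `cell_id`, `nuclear_mean`,
#'   `cyto_mean`, `cn`, centroid `row`/`col`, `measurable`.
#' @export
measure_cells <- function(reporter, masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  if (!all(dim(reporter) == dim(masks$labels))) {
    stop("measure_cells: reporter and masks dimensions differ")
  }
  ids <- masks$cells
  nr <- nrow(masks$labels)
  rows <- lapply(ids, function(id) {
    nucv <- reporter[masks$nuclear == id]
    cytv <- reporter[masks$ring == id]
    nm <- if (length(nucv)) mean(nucv) else NA_real_
    cm <- if (length(cytv)) mean(cytv) else NA_real_
    ok <- is.finite(nm) && is.finite(cm) && nm > 0
    px <- which(masks$labels == id)
    data.frame(cell_id = id, nuclear_mean = nm, cyto_mean = cm,
               cn = if (ok) cm / nm else NA_real_,
               row = mean(((px - 1L) %% nr) + 1L),
               col = mean(((px - 1L) %/% nr) + 1L),
               measurable = ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Link per-frame detections into trajectories (greedy nearest neighbor)
#'
#' Successive frames are linked by repeatedly joining the globally
#' closest (track, detection) pair closer than `max_disp` pixels.
#' Detections that cannot be linked start new tracks; frames in which a
#' track has no detection become missing points.
#'
#' @param frames list of data.frames (one per frame) with centroid
#'   columns `row`, `col` plus any measurement columns (e.g. `cn`).
#' @param max_disp maximum linking displacement, pixels.
#' @return data.frame with `track_id`, `frame`, `row`, `col`, `missing`
#'   and any carried measurement columns (NA where missing).
#' @export
link_frames <- function(frames, max_disp) {
  stopifnot(length(frames) >= 1)
  n_frames <- length(frames)
  carry <- setdiff(names(frames[[1L]]), c("row", "col"))
  tracks <- list()  # each: list(last_row, last_col, hits = list(frame -> det idx))
  new_track <- function(r, c, fr, di) {
    list(row = r, col = c, det = setNames(list(di), as.character(fr)))
  }
  f1 <- frames[[1L]]
  for (i in seq_len(nrow(f1))) {
    tracks[[length(tracks) + 1L]] <- new_track(f1$row[i], f1$col[i], 1L, i)
  }
  if (n_frames > 1L) for (fr in 2:n_frames) {
    det <- frames[[fr]]
    nd <- nrow(det)
    nt <- length(tracks)
    used_d <- rep(FALSE, nd)
    used_t <- rep(FALSE, nt)
    if (nd > 0L && nt > 0L) {
      tr_pos <- t(vapply(tracks, function(t) c(t$row, t$col), numeric(2)))
      dmat <- outer(tr_pos[, 1L], det$row, "-")^2 +
        outer(tr_pos[, 2L], det$col, "-")^2
      dmat <- sqrt(matrix(dmat, nt, nd))
      repeat {
        dmat[used_t, ] <- Inf
        dmat[, used_d] <- Inf
        k <- which.min(dmat)
        if (!length(k) || !is.finite(dmat[k]) || dmat[k] > max_disp) break
        ti <- ((k - 1L) %% nt) + 1L
        di <- ((k - 1L) %/% nt) + 1L
        tracks[[ti]]$row <- det$row[di]
        tracks[[ti]]$col <- det$col[di]
        tracks[[ti]]$det[[as.character(fr)]] <- di
        used_t[ti] <- TRUE
        used_d[di] <- TRUE
      }
    }
    for (di in which(!used_d)) {
      tracks[[length(tracks) + 1L]] <- new_track(det$row[di], det$col[di], fr, di)
    }
  }
  out <- list()
  for (ti in seq_along(tracks)) {
    hit_frames <- as.integer(names(tracks[[ti]]$det))
    span <- min(hit_frames):max(hit_frames)
    for (fr in span) {
      di <- tracks[[ti]]$det[[as.character(fr)]]
      if (is.null(di)) {
        row <- data.frame(track_id = ti, frame = fr, row = NA_real_,
                          col = NA_real_, missing = TRUE)
        for (cc in carry) row[[cc]] <- NA
      } else {
        d <- frames[[fr]][di, , drop = FALSE]
        row <- data.frame(track_id = ti, frame = fr, row = d$row,
                          col = d$col, missing = FALSE)
        for (cc in carry) row[[cc]] <- d[[cc]]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
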