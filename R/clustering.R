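#' Dynamic 4D PET image
#'
#' A 4D activity array (x, y, z, frame) with its frame schedule, voxel size
#' and named binary masks (e.g. `WB`, `GM`, `WM`).
#'
#' @param voxels 4D numeric array, frame axis last, kBq/mL.
#' @param grid a [time_grid]; its length must match the frame axis.
#' @param voxel_size 3-vector, mm.
#' @param masks named list of 3D logical arrays matching the spatial shape.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(voxels, grid, voxel_size = c(1, 1, 1),
                          masks = list()) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4,
            inherits(grid, "time_grid"))
  if (dim(voxels)[4L] != length(grid))
    stop("frame axis (", dim(voxels)[4L], ") does not match grid (",
         length(grid), ")")
  sp <- dim(voxels)[1:3]
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), as.integer(sp)) && !identical(dim(m), sp))
      stop("mask '", nm, "' does not match the spatial shape")
    masks[[nm]] <- array(as.logical(m), dim = sp)
  }
  structure(list(voxels = voxels, grid = grid,
                 voxel_size = as.numeric(voxel_size), masks = masks),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels, %d frames; masks: %s\n",
              d[1L], d[2L], d[3L], d[4L],
              if (length(x$masks)) paste(names(x$masks), collapse = ", ")
              else "(none)"))
  invisible(x)
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable zero-padded Gaussian blur of a 3D array
gauss_blur_3d <- function(vol, sigma) {
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2
  d <- dim(vol)
  for (ax in 1:3) {
    out <- array(0, dim = d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      n <- d[ax]
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      if (!any(ok)) next
      dst_idx <- which(ok)
      src_idx <- src[ok]
      if (ax == 1L) out[dst_idx, , ] <- out[dst_idx, , ] +
          k[j] * vol[src_idx, , ]
      else if (ax == 2L) out[, dst_idx, ] <- out[, dst_idx, ] +
          k[j] * vol[, src_idx, ]
      else out[, , dst_idx] <- out[, , dst_idx] + k[j] * vol[, , src_idx]
    }
    vol <- out
  }
  vol
}

#' HYPR-style composite-guided denoising
#'
#' Spatial denoising that preserves temporal dynamics, used only to
#' stabilize TAC clustering (never for quantification): each frame is
#' replaced by `C * (G x frame) / (G x C + eps)`, where `C` is the
#' duration-weighted time-summed composite image and `G` a Gaussian kernel
#' of standard deviation `sigma_voxels`.
#'
#' @param img a [dynamic_image].
#' @param sigma_voxels Gaussian kernel standard deviation, voxels
#'   (default 3); supply `sigma_mm` instead to give it in millimetres
#'   (converted with the mean voxel size).
#' @param sigma_mm optional kernel width in mm (overrides `sigma_voxels`).
#' @return A denoised [dynamic_image] (same grid and masks).
#' @export
hypr_denoise <- function(img, sigma_voxels = 3, sigma_mm = NULL) {
  stopifnot(inherits(img, "dynamic_image"))
  if (!is.null(sigma_mm)) sigma_voxels <- sigma_mm / mean(img$voxel_size)
  if (sigma_voxels <= 0) stop("sigma must be positive")
  eps <- 1e-12
  nt <- dim(img$voxels)[4L]
  dur <- img$grid$frame_duration
  comp <- array(0, dim = dim(img$voxels)[1:3])
  for (f in seq_len(nt)) comp <- comp + dur[f] * img$voxels[, , , f]
  if (all(img$voxels == 0)) return(img)
  if (all(comp == 0)) stop("all-zero composite image: cannot denoise")
  comp_s <- gauss_blur_3d(comp, sigma_voxels)
  out <- img$voxels
  for (f in seq_len(nt)) {
    fr_s <- gauss_blur_3d(img$voxels[, , , f], sigma_voxels)
    out[, , , f] <- comp * fr_s / (comp_s + eps)
  }
  res <- img
  res$voxels <- out
  res
}

# Voronoi-iteration k-medoids under Euclidean distance.
# X: n x T matrix. Returns medoid indices, assignments and the per-iteration
# objective trace (sum of distances of every point to its medoid).
kmedoids_once <- function(X, k, max_iter) {
  n <- nrow(X)
  med <- sample.int(n, k)
  dist_to <- function(ids) {
    # n x k matrix of Euclidean distances to the rows in ids
    d2 <- outer(rowSums(X^2), rowSums(X[ids, , drop = FALSE]^2), "+") -
      2 * X %*% t(X[ids, , drop = FALSE])
    sqrt(pmax(d2, 0))
  }
  assign_cost <- function(med) {
    D <- dist_to(med)
    lab <- max.col(-D, ties.method = "first")
    # reseed any empty cluster with the point farthest from its medoid
    for (tries in seq_len(k)) {
      empty <- setdiff(seq_len(k), unique(lab))
      if (!length(empty)) break
      dmin <- D[cbind(seq_len(n), lab)]
      for (c in empty) {
        far <- which.max(dmin)
        med[c] <- far
        dmin[far] <- -Inf
      }
      D <- dist_to(med)
      lab <- max.col(-D, ties.method = "first")
    }
    list(lab = lab, cost = sum(D[cbind(seq_len(n), lab)]), med = med)
  }
  cur <- assign_cost(med)
  med <- cur$med
  trace <- cur$cost
  for (it in seq_len(max_iter)) {
    new_med <- med
    for (c in seq_len(k)) {
      ids <- which(cur$lab == c)
      if (!length(ids)) next
      Dc <- as.matrix(stats::dist(X[ids, , drop = FALSE]))
      new_med[c] <- ids[which.min(rowSums(Dc))]
    }
    if (all(sort(new_med) == sort(med))) break
    nxt <- assign_cost(new_med)
    if (nxt$cost > cur$cost + 1e-12) break  # safeguard; should not increase
    med <- nxt$med
    cur <- nxt
    trace <- c(trace, cur$cost)
  }
  list(medoids = med, labels = cur$lab, cost = cur$cost, trace = trace)
}

#' Cluster voxel TACs by functional similarity
#'
#' Partitions the in-mask voxel TACs of a (HYPR-denoised) dynamic image into
#' `k` groups by k-medoids under Euclidean distance on the raw frame values,
#' with seeded random restarts (best within-cluster cost wins) and a
#' per-restart iteration cap. Cluster mean TACs are computed from the
#' *original* (non-denoised) image, since the denoised signal is biased and
#' only serves the partitioning.
#'
#' @param img a [dynamic_image] (the original, quantitative image).
#' @param mask_name name of the mask in `img$masks` to cluster within.
#' @param k number of clusters (must not exceed the number of distinct TACs).
#' @param seed integer seed; the same seed yields an identical partition.
#' @param n_restarts random restarts (default 10).
#' @param max_iter iteration cap per restart (default 500).
#' @param denoise apply [hypr_denoise] before clustering (default TRUE).
#' @param sigma_voxels kernel width for the denoising step.
#' @param tissue_class tag attached to every cluster (e.g. `"GM"`).
#' @return An object of class `cluster_set`: `labels` (3D integer array,
#'   0 = outside mask), `medoid_tacs`, `mean_tacs` (from the original
#'   image), `sizes`, `cost`, `trace` (objective per iteration of the
#'   winning restart), `restart_costs`, `tissue_class`.
#' @export
cluster_tacs <- function(img, mask_name, k, seed = 1L, n_restarts = 10,
                         max_iter = 500, denoise = TRUE, sigma_voxels = 3,
                         tissue_class = mask_name) {
  stopifnot(inherits(img, "dynamic_image"))
  mask <- img$masks[[mask_name]]
  if (is.null(mask)) stop("no mask named '", mask_name, "'")
  ids <- which(mask)
  if (!length(ids)) stop("mask '", mask_name, "' is empty")
  src <- if (denoise) hypr_denoise(img, sigma_voxels) else img
  nt <- dim(img$voxels)[4L]
  nvox <- prod(dim(img$voxels)[1:3])
  Xd <- matrix(src$voxels, nrow = nvox)[ids, , drop = FALSE]
  Xo <- matrix(img$voxels, nrow = nvox)[ids, , drop = FALSE]
  if (k > nrow(unique(Xd)))
    stop("k = ", k, " exceeds the number of distinct TACs")
  runs <- local_seed(seed, lapply(seq_len(n_restarts), function(r)
    kmedoids_once(Xd, k, max_iter)))
  costs <- vapply(runs, `[[`, 0, "cost")
  best <- runs[[which.min(costs)]]
  # relabel clusters by decreasing size (ties by lower original index)
  sizes <- tabulate(best$labels, nbins = k)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k); remap[ord] <- seq_len(k)
  lab <- remap[best$labels]
  med <- best$medoids[ord]
  sizes <- sizes[ord]
  labels <- array(0L, dim = dim(mask))
  labels[ids] <- lab
  mk_tac <- function(v, lbl) tac(img$grid, v, label = lbl)
  mean_tacs <- lapply(seq_len(k), function(c)
    mk_tac(colMeans(Xo[lab == c, , drop = FALSE]),
           paste0(tissue_class, "-cluster-", c)))
  medoid_tacs <- lapply(seq_len(k), function(c)
    mk_tac(Xo[med[c], ], paste0(tissue_class, "-medoid-", c)))
  structure(list(labels = labels, medoid_tacs = medoid_tacs,
                 mean_tacs = mean_tacs, sizes = sizes, cost = best$cost,
                 trace = best$trace, restart_costs = costs,
                 all_traces = lapply(runs, `[[`, "trace"),
                 tissue_class = tissue_class, k = k, seed = seed),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %s: k=%d, sizes [%s], cost=%.5g\n",
              x$tissue_class, x$k, paste(x$sizes, collapse = ", "), x$cost))
  invisible(x)
}

earliest_peak_index <- function(cs) {
  pk <- vapply(cs$mean_tacs, function(tc)
    tc$grid$mid_time[which.max(tc$values)], 0)
  which.min(pk)
}

#' Select the largest clusters per tissue class
#'
#' Returns the `n_per_class` largest clusters of each supplied cluster set
#' as mean TACs, ordered GM-then-WM (first set first) and size-descending
#' within each set; ties break towards the lower cluster index. With
#' `exclude_nonbrain = TRUE` the cluster whose mean TAC peaks earliest (a
#' vascular/non-brain signature) is dropped from each set before selection.
#'
#' @param cs_gm a `cluster_set` (e.g. grey matter).
#' @param cs_wm optional second `cluster_set` (e.g. white matter).
#' @param n_per_class clusters kept per set (default 3).
#' @param exclude_nonbrain drop the earliest-peaking cluster first.
#' @return List of mean [tac]s.
#' @export
select_clusters <- function(cs_gm, cs_wm = NULL, n_per_class = 3,
                            exclude_nonbrain = FALSE) {
  pick <- function(cs) {
    stopifnot(inherits(cs, "cluster_set"))
    keep <- seq_len(cs$k)
    if (exclude_nonbrain && cs$k > 1L) {
      drop <- earliest_peak_index(cs)
      message("excluding cluster ", drop, " of ", cs$tissue_class,
              " (earliest-peaking mean TAC; presumed non-brain)")
      keep <- setdiff(keep, drop)
    }
    # sizes are already sorted descending with first-index tie-break
    cs$mean_tacs[keep[seq_len(min(n_per_class, length(keep)))]]
  }
  out <- pick(cs_gm)
  if (!is.null(cs_wm)) out <- c(out, pick(cs_wm))
  out
}
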