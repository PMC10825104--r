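#' Literature microparameters of the six-region simulation study
#'
#' Rate constants for six theoretical VOIs with deliberately distinct FDG
#' kinetics (drawn from published human FDG studies) plus the whole-brain
#' (WB) parameter set used to generate the WB TAC. `kf` and `Ki` are derived
#' from the primary four columns. Note: the WB row's `Vb` (0.067) is a
#' canonical whole-brain blood-volume value rather than the arithmetic mean
#' of the six regional `Vb` entries (several of which are placeholders).
#'
#' @return A data.frame with columns `voi`, `K1`, `k2`, `k3`, `Vb`, `kf`,
#'   `Ki` (rates in the units of [micro_params]).
#' @export
voi_microparameters <- function() {
  d <- data.frame(
    voi = c(paste0("VOI", 1:6), "WB"),
    K1 = c(0.105, 0.123, 0.096, 0.088, 0.069, 0.062, 0.090),
    k2 = c(0.148, 0.121, 0.109, 0.123, 0.129, 0.071, 0.117),
    k3 = c(0.074, 0.079, 0.042, 0.071, 0.064, 0.067, 0.066),
    Vb = c(0.050, 0.059, 0.050, 0.084, 0.050, 0.050, 0.067))
  d$kf <- d$k2 + d$k3
  d$Ki <- d$K1 * d$k3 / d$kf
  d
}

#' Reference simulation: AIF, six regional TACs, WB TAC and anchors
#'
#' Regenerates the package's ground-truth simulation study: a noiseless
#' human-like bolus input from the exponential input model with population
#' constants `A1 = 850` a.u./min, `A2 = 22`, `A3 = 21` a.u.,
#' `lambda = (4, 0.12, 0.01)` 1/min and no delay, sampled on the 50-frame
#' clinical schedule; six regional TACs generated by the forward 2TCM from
#' [voi_microparameters()] (with `Cb = Cp`, i.e. `R = 1`); a whole-brain TAC
#' from the WB parameter row; and two anchors read from the *analytic* input
#' at 28.5 and 53.5 min (both frame mid-times of the schedule). Fully
#' deterministic.
#'
#' @param grid [time_grid] to sample on (default [human_frame_grid()]).
#' @param anchor_times anchor sampling times, minutes.
#' @return A list: `aif` ([tac]), `region_tacs` (list of 6 [tac]s), `wb_tac`
#'   ([tac]), `anchors` (data.frame `time_min`, `conc`), `truth` (the
#'   parameter table), `feng` ([feng_params]), `R` (= 1).
#' @export
reference_simulation <- function(grid = human_frame_grid(),
                                 anchor_times = c(28.5, 53.5)) {
  fp <- feng_params(850, 22, 21, 4, 0.12, 0.01, 0)
  aif <- feng_input(fp, grid)
  tab <- voi_microparameters()
  reg <- tab[tab$voi != "WB", ]
  region_tacs <- lapply(seq_len(nrow(reg)), function(i) {
    p <- micro_params(reg$K1[i], reg$k2[i], reg$k3[i], reg$Vb[i])
    ct <- twotcm_forward(p, aif, R = 1)
    ct$label <- reg$voi[i]
    ct
  })
  wbrow <- tab[tab$voi == "WB", ]
  wb_p <- micro_params(wbrow$K1, wbrow$k2, wbrow$k3, wbrow$Vb)
  wb_tac <- twotcm_forward(wb_p, aif, R = 1)
  wb_tac$label <- "WB"
  anchors <- data.frame(time_min = anchor_times,
                        conc = feng_input(fp, anchor_times))
  list(aif = aif, region_tacs = region_tacs, wb_tac = wb_tac,
       anchors = anchors, truth = tab, feng = fp, R = 1)
}

#' Phantom specification
#'
#' Describes a synthetic study: named regions with their [micro_params] (and
#' voxel counts for the image phantom), an input model, a frame schedule, a
#' blood-to-plasma ratio and an optional frame-noise model with per-frame
#' variance proportional to `value / duration`.
#'
#' @param regions list of `list(label =, params = micro_params, voxel_count =,
#'   tissue =)` entries (`voxel_count` default 100, `tissue` default "GM").
#' @param aif a [feng_params] input model.
#' @param grid a [time_grid].
#' @param R blood-to-plasma ratio (default 1).
#' @param noise_scale noise magnitude (>= 0; 0 = noiseless). Frame noise is
#'   Gaussian with `sd_i = noise_scale * sqrt(max(value_i, 0) / duration_i)`.
#' @param seed integer RNG seed for noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(regions, aif, grid, R = 1, noise_scale = 0,
                         seed = 1L) {
  stopifnot(is.list(regions), inherits(aif, "feng_params"),
            inherits(grid, "time_grid"), noise_scale >= 0)
  labels <- vapply(regions, function(r) as.character(r$label), "")
  if (anyDuplicated(labels)) stop("region labels must be unique")
  regions <- lapply(regions, function(r) {
    stopifnot(inherits(r$params, "micro_params"))
    if (is.null(r$voxel_count)) r$voxel_count <- 100L
    if (is.null(r$tissue)) r$tissue <- "GM"
    r
  })
  structure(list(regions = regions, aif = aif, grid = grid, R = R,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

noise_sd <- function(values, grid, scale) {
  scale * sqrt(pmax(values, 0) / grid$frame_duration)
}

#' Generate regional TACs from a phantom specification
#'
#' Each region's TAC is the forward 2TCM of its parameters driven by the
#' specified input model (with `Cb = R * Cp`), with optional seeded Gaussian
#' frame noise whose variance is proportional to `value / duration`.
#'
#' @param spec a [phantom_spec].
#' @return Named list of [tac]s, one per region.
#' @export
generate_tacs <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cp <- feng_input(spec$aif, spec$grid)
  out <- local_seed(spec$seed, lapply(spec$regions, function(r) {
    ct <- twotcm_forward(r$params, cp, R = spec$R)
    if (spec$noise_scale > 0) {
      v <- ct$values +
        stats::rnorm(length(ct$values),
                     sd = noise_sd(ct$values, spec$grid, spec$noise_scale))
      v[1L] <- max(v[1L], 0)
      ct <- tac(spec$grid, v, label = r$label)
    } else ct$label <- r$label
    ct
  }))
  names(out) <- vapply(spec$regions, function(r) r$label, "")
  out
}

#' Voxelized 4D phantom for clustering tests
#'
#' Lays the phantom regions out as spatially compact slabs along the first
#' axis of a small volume (so composite-guided denoising mixes only true
#' neighbours), fills each voxel with its region's noiseless TAC plus
#' independent voxel-level noise (same frame-variance model as
#' [generate_tacs]), and builds WB/GM/WM masks from the region tissue tags.
#' The ground-truth region label of every voxel is returned in `labels`.
#'
#' @param spec a [phantom_spec]; region `voxel_count`s must sum to at most
#'   `prod(shape)`.
#' @param shape 3-vector of volume extents (default `c(20, 20, 10)`).
#' @return A [dynamic_image] whose `masks` include `WB`, `GM`, `WM`, with an
#'   extra field `labels` (3D integer array, 0 = background).
#' @export
generate_phantom_image <- function(spec, shape = c(20, 20, 10)) {
  stopifnot(inherits(spec, "phantom_spec"), length(shape) == 3)
  counts <- vapply(spec$regions, function(r) as.integer(r$voxel_count), 1L)
  nvox <- prod(shape)
  if (sum(counts) > nvox)
    stop("region voxel counts exceed the volume (", nvox, " voxels)")
  cp <- feng_input(spec$aif, spec$grid)
  clean <- lapply(spec$regions, function(r)
    twotcm_forward(r$params, cp, R = spec$R)$values)
  nt <- length(spec$grid)
  labels <- array(0L, dim = shape)
  vox <- array(0, dim = c(shape, nt))
  flat <- matrix(0, nrow = nvox, ncol = nt)
  noise <- local_seed(spec$seed, lapply(seq_along(spec$regions), function(i) {
    if (spec$noise_scale == 0) return(NULL)
    sd_i <- noise_sd(clean[[i]], spec$grid, spec$noise_scale)
    matrix(stats::rnorm(counts[i] * nt, sd = rep(sd_i, each = counts[i])),
           nrow = counts[i])
  }))
  # contiguous slabs along x, each wide enough for its voxel count; voxels
  # beyond the count stay background within the slab
  per_plane <- prod(shape[2:3])
  x_hi <- 0L
  for (i in seq_along(spec$regions)) {
    width <- ceiling(counts[i] / per_plane)
    x_lo <- x_hi + 1L
    x_hi <- x_hi + width
    if (x_hi > shape[1L])
      stop("regions do not fit as slabs along x; enlarge the volume")
    slab <- which(slice.index(labels, 1L) >= x_lo &
                    slice.index(labels, 1L) <= x_hi)
    ids <- slab[seq_len(counts[i])]
    labels[ids] <- i
    block <- matrix(clean[[i]], nrow = counts[i], ncol = nt, byrow = TRUE)
    if (!is.null(noise[[i]])) block <- block + noise[[i]]
    flat[ids, ] <- block
  }
  vox[] <- flat
  tissue <- vapply(spec$regions, function(r) r$tissue, "")
  in_mask <- labels > 0L
  masks <- list(WB = in_mask,
                GM = array(labels %in% which(tissue == "GM"), dim = shape),
                WM = array(labels %in% which(tissue == "WM"), dim = shape))
  img <- dynamic_image(vox, spec$grid, masks = masks)
  img$labels <- labels
  img
}
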