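# End-to-end pipeline runner with a reproducibility manifest:
# simulate -> preprocess -> embed/endmembers -> unmix -> framescan ->
# segment, each stage writing artifacts under a run directory.

#' Default pipeline configuration
#'
#' Per-stage sections mirroring the workflow's standard parameters;
#' any value can be overridden in a user config (YAML file or list).
#' The phantom stages default to desk scale (96 x 96 px, 250 channels,
#' 20 frames); preprocessing on phantoms applies only the mean kernel
#' since phantoms are generated at the reduced dimension.
#'
#' @param seed Master seed recorded for every stochastic stage.
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    simulate = list(phantom = "default", rows = 96, cols = 96,
                    n_channels = 250, n_frames = 20,
                    counts_per_pixel_per_frame = 250, seed = seed),
    preprocess = list(drop_first_channels = 0, spatial_bin = 1,
                      spectral_bin = 1, mean_kernel_px = 3),
    embed = list(fraction = 0.2, backend = "umap", smooth_sigma = 1,
                 exclude_central_bulk = FALSE, box_halfwidth_bins = 2,
                 seed = seed),
    framescan = list(frame_counts = 2^(0:5), pixels_per_class = 60,
                     seed = seed),
    segment = list(blur_sigma_px = 4, threshold = 0.4,
                   min_peak_distance_px = 10, close_radius_px = 0,
                   rel_threshold = 0.5))
}

.requireKeys <- function(config) {
  need <- list(
    simulate = c("phantom", "rows", "cols", "n_frames",
                 "counts_per_pixel_per_frame", "seed"),
    preprocess = c("drop_first_channels", "spatial_bin", "spectral_bin",
                   "mean_kernel_px"),
    embed = c("fraction", "backend", "seed"),
    framescan = c("frame_counts", "pixels_per_class"),
    segment = c("blur_sigma_px", "threshold", "min_peak_distance_px"))
  for (stage in names(need)) {
    if (is.null(config[[stage]]))
      stop("missing config key: ", stage)
    for (key in need[[stage]])
      if (is.null(config[[stage]][[key]]))
        stop("missing config key: ", stage, "$", key)
  }
  invisible(TRUE)
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full phantom pipeline
#'
#' Executes simulate, preprocess, embedding-driven endmember
#' extraction, NNLS unmixing with global scaling, frame-accumulation
#' distance curves, and prompt-driven segmentation with the fallback
#' segmenter. Every stage writes its artifacts under `out_dir`
#' (append-only; re-running into a non-empty directory requires
#' `overwrite = TRUE`), and a reproducibility manifest records the
#' config snapshot, seeds, package version and per-artifact checksums.
#'
#' @param config Configuration list (see [defaultPipelineConfig()]) or
#'   path to a YAML file with the same structure.
#' @param out_dir Run directory, created if needed.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with the manifest and the key in-memory
#'   results (`cube`, `truth`, `endmembers`, `stack`, `curves`,
#'   `masks`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), out_dir,
                        overwrite = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  .requireKeys(config)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("run directory ", out_dir, " is not empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  add <- function(path) artifacts <<- c(artifacts, path)
  stamp <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    stamp[[name]] <<- list(started = format(t0, usetz = TRUE),
                           seconds = as.numeric(Sys.time() - t0))
    res
  }

  # --- simulate ------------------------------------------------------
  sim <- config$simulate
  energy <- EnergyAxis(40, 80, sim$n_channels %||% 250)
  spec <- stage("simulate", switch(as.character(sim$phantom),
    default = defaultPhantom(sim$rows, sim$cols,
                             sim$counts_per_pixel_per_frame, sim$n_frames,
                             sim$seed, energy = energy),
    fourclass = fourClassPhantom(sim$rows, sim$cols,
                                 sim$counts_per_pixel_per_frame,
                                 sim$n_frames, sim$seed, energy = energy),
    readPhantomSpec(sim$phantom)))
  rendered <- renderPhantom(spec)
  cube_path <- file.path(out_dir, "cube.edx")
  add(writeCube(rendered$cube, cube_path)); add(cube_path)
  spec_path <- file.path(out_dir, "phantom.yaml")
  add(writePhantomSpec(spec, spec_path))

  # --- preprocess ----------------------------------------------------
  pcfg <- do.call(preprocessConfig, config$preprocess)
  cube <- stage("preprocess", preprocessCube(rendered$cube, pcfg))

  # --- embed + endmembers -------------------------------------------
  e <- config$embed
  disc <- stage("embed", discoverEndmembers(cube,
    fraction = e$fraction, seed = e$seed, backend = e$backend,
    bins = e$bins, min_distance_bins = e$min_distance_bins,
    min_count = e$min_count,
    smooth_sigma = e$smooth_sigma %||% 1,
    exclude_central_bulk = isTRUE(e$exclude_central_bulk),
    box_halfwidth_bins = e$box_halfwidth_bins %||% 2))
  em <- disc$endmembers
  em_path <- file.path(out_dir, "endmembers.tsv")
  add(.writeTsv(as.data.frame(t(emSpectra(em)),
                              col.names = emLabels(em)), em_path))
  add(.writeTsv(disc$maxima, file.path(out_dir, "embedding_maxima.tsv")))

  # --- unmix ---------------------------------------------------------
  stack <- stage("unmix", finalizeScale(nnlsUnmix(cube, em)))
  imgs <- abundanceToImages(stack, dir = file.path(out_dir, "abundance"))
  for (f in imgs$files) add(f)

  # --- framescan -----------------------------------------------------
  fs <- config$framescan
  curves <- stage("framescan", distanceVsFrames(spec,
    frame_counts = fs$frame_counts,
    pixels_per_class = fs$pixels_per_class,
    seed = fs$seed %||% sim$seed))
  add(.writeTsv(data.frame(frame_count = curves@frame_counts,
                           t(curves@intra), check.names = FALSE),
                file.path(out_dir, "intra_distance.tsv")))
  add(.writeTsv(data.frame(frame_count = curves@frame_counts,
                           mean_ratio = curves@mean_ratio),
                file.path(out_dir, "distance_ratio.tsv")))

  # --- segment -------------------------------------------------------
  sg <- config$segment
  pc <- promptConfig(blur_sigma_px = sg$blur_sigma_px,
                     threshold = sg$threshold,
                     min_peak_distance_px = sg$min_peak_distance_px,
                     close_radius_px = sg$close_radius_px %||% 0)
  masks <- stage("segment", {
    sc <- scaledAbundances(stack)
    ml <- list()
    for (k in seq_len(nEndmembers(em))) {
      amap <- sc[, , k]
      prompts <- promptsFromAbundance(amap, pc, label = emLabels(em)[k])
      if (!nrow(promptPoints(prompts))) next
      seg <- segmentWithPrompts(amap, prompts,
        segmenter = fallbackSegmenter(sg$rel_threshold %||% 0.5),
        close_radius = pc$close_radius_px)
      ml[[emLabels(em)[k]]] <- maskList(seg)[[1]]
    }
    if (!length(ml)) stop("no structure produced any prompts")
    SegmentationMasks(ml)
  })
  seg_dir <- file.path(out_dir, "masks")
  dir.create(seg_dir, showWarnings = FALSE)
  for (l in masks@labels) {
    f <- file.path(seg_dir, paste0("mask_", l, ".png"))
    png::writePNG(masks@masks[[l]] * 1, f)
    add(f)
  }
  comp <- compositeMasks(masks)
  f <- file.path(seg_dir, "composite.png")
  png::writePNG(comp / max(1, max(comp)), f)
  add(f)

  # --- manifest ------------------------------------------------------
  manifest <- list(
    package = "EDXUnmix",
    version = as.character(utils::packageVersion("EDXUnmix")),
    config = config,
    seeds = list(simulate = sim$seed, embed = e$seed,
                 framescan = fs$seed %||% sim$seed),
    stages = stamp,
    artifacts = lapply(setNames(nm = artifacts), function(p)
      unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, cube = cube,
                 truth = rendered$truth, endmembers = em, stack = stack,
                 curves = curves, masks = masks))
}

#' Match discovered endmembers to reference spectra
#'
#' Greedy assignment by cosine similarity: reference classes are
#' matched to their most similar discovered endmember, best pairs
#' first, without reuse.
#'
#' @param endmembers An [EndmemberSet-class].
#' @param reference Matrix `[class, channel]` of reference spectra.
#' @return data.frame with `reference` (row index), `endmember`
#'   (matched index) and `cosine`.
#' @export
matchEndmembers <- function(endmembers, reference) {
  E <- emSpectra(endmembers)
  if (ncol(E) != ncol(reference))
    stop("channel count mismatch between endmembers and reference")
  sim <- matrix(0, nrow(reference), nrow(E))
  for (i in seq_len(nrow(reference))) for (j in seq_len(nrow(E)))
    sim[i, j] <- cosineSimilarity(reference[i, ], E[j, ])
  out <- data.frame(reference = integer(), endmember = integer(),
                    cosine = numeric())
  avail_r <- seq_len(nrow(reference)); avail_e <- seq_len(nrow(E))
  while (length(avail_r) && length(avail_e)) {
    sub <- sim[avail_r, avail_e, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(reference = avail_r[ij[1]],
                                 endmember = avail_e[ij[2]],
                                 cosine = sub[ij[1], ij[2]]))
    avail_r <- avail_r[-ij[1]]; avail_e <- avail_e[-ij[2]]
  }
  out[order(out$reference), , drop = FALSE]
}
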