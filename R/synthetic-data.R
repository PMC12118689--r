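# Synthetic EDX phantoms: linear mixtures of per-structure spectra
# (Gaussian characteristic lines + exponentially decaying continuum),
# Poisson counting noise accumulated over frames. These phantoms carry
# the statistical structure the downstream workflow assumes and provide
# ground truth for every stage.

#' Generative spectral model of one structure class
#'
#' Characteristic X-ray lines are Gaussians on the energy axis
#' (integrated channel-wise), the Bremsstrahlung-like continuum an
#' exponentially decaying density. Amplitudes are total line areas in
#' expected counts; the expected spectrum is nonnegative everywhere.
#'
#' @slot lines data.frame with columns `energy_ev`, `width_ev` (Gaussian
#'   sd), `amplitude` (line area, >= 0).
#' @slot continuum_scale Continuum density at 0 eV (>= 0).
#' @slot continuum_decay_ev Exponential decay constant (eV, > 0).
#' @export
setClass("SpectralModel",
  representation(lines = "data.frame", continuum_scale = "numeric",
                 continuum_decay_ev = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("energy_ev", "width_ev", "amplitude")
    if (nrow(object@lines) && !all(need %in% names(object@lines)))
      msg <- c(msg, "lines must have columns energy_ev, width_ev, amplitude")
    else if (nrow(object@lines)) {
      if (any(object@lines$amplitude < 0))
        msg <- c(msg, "line amplitudes must be >= 0")
      if (any(object@lines$width_ev <= 0))
        msg <- c(msg, "line widths must be > 0")
    }
    if (object@continuum_scale < 0)
      msg <- c(msg, "continuum_scale must be >= 0")
    if (object@continuum_decay_ev <= 0)
      msg <- c(msg, "continuum_decay_ev must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @param lines data.frame(energy_ev, width_ev, amplitude); may be empty.
#' @param continuum_scale Continuum density scale (counts per eV at 0 eV).
#' @param continuum_decay_ev Continuum decay constant in eV.
#' @rdname SpectralModel-class
#' @export
spectralModel <- function(lines = data.frame(energy_ev = numeric(),
                                             width_ev = numeric(),
                                             amplitude = numeric()),
                          continuum_scale = 0,
                          continuum_decay_ev = 3000) {
  new("SpectralModel", lines = lines,
      continuum_scale = as.numeric(continuum_scale),
      continuum_decay_ev = as.numeric(continuum_decay_ev))
}

#' Expected spectrum of a spectral model on an energy axis
#'
#' Integrates each Gaussian line and the exponential continuum over the
#' channel bins (channel i spans `center +- bin_width/2`), so the sum
#' over channels equals the analytic line areas plus continuum integral
#' whenever the axis covers their support.
#'
#' @param model A [SpectralModel-class].
#' @param axis An [EnergyAxis-class].
#' @return Nonnegative numeric vector of length `n_channels` (expected
#'   counts per channel).
#' @export
expectedSpectrum <- function(model, axis) {
  stopifnot(is(model, "SpectralModel"), is(axis, "EnergyAxis"))
  centers <- channelEnergies(axis)
  lo <- centers - axis@bin_width_ev / 2
  hi <- centers + axis@bin_width_ev / 2
  out <- numeric(axis@n_channels)
  if (nrow(model@lines)) {
    for (i in seq_len(nrow(model@lines))) {
      ln <- model@lines[i, ]
      out <- out + ln$amplitude *
        (pnorm(hi, ln$energy_ev, ln$width_ev) -
         pnorm(lo, ln$energy_ev, ln$width_ev))
    }
  }
  if (model@continuum_scale > 0) {
    d <- model@continuum_decay_ev
    out <- out + model@continuum_scale * d *
      (exp(-pmax(lo, 0) / d) - exp(-pmax(hi, 0) / d))
  }
  pmax(out, 0)
}

# ---------------------------------------------------------------------------
# PhantomSpec / GroundTruth
# ---------------------------------------------------------------------------

#' Specification of a synthetic EDX phantom
#'
#' Describes a scene of geometric structures (disks, ellipses, annuli,
#' bands, or the diffuse background filling the remainder), each with
#' its own [SpectralModel-class] and fractional abundance, plus the
#' counting statistics: expected total counts per pixel per frame,
#' number of accumulated frames, and the RNG seed that fully determines
#' the rendered cube.
#'
#' @slot shape Integer `(rows, cols)`.
#' @slot structures List of structure descriptions (see
#'   [phantomStructure()]).
#' @slot counts_per_pixel_per_frame Expected total counts in a pure
#'   pixel per frame.
#' @slot n_frames Accumulated frame count.
#' @slot seed Integer seed.
#' @slot energy [EnergyAxis-class] of the rendered cube.
#' @slot pixel_size_nm Pixel size (nm).
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", structures = "list",
                 counts_per_pixel_per_frame = "numeric",
                 n_frames = "integer", seed = "integer",
                 energy = "EnergyAxis", pixel_size_nm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 2 || any(object@shape < 1))
      msg <- c(msg, "shape must be (rows, cols) >= 1")
    if (object@counts_per_pixel_per_frame < 0)
      msg <- c(msg, "counts_per_pixel_per_frame must be >= 0")
    if (object@n_frames < 1L)
      msg <- c(msg, "n_frames must be >= 1")
    if (!length(object@structures))
      msg <- c(msg, "at least one structure is required")
    if (length(msg)) msg else TRUE
  })

#' Describe one phantom structure
#'
#' @param label Structure label.
#' @param model Its [SpectralModel-class].
#' @param geometry List of geometric primitives, each a list with
#'   `type` one of `"disk"` (`center`, `radius`), `"ellipse"` (`center`,
#'   `semi_axes`), `"annulus"` (`center`, `r_inner`, `r_outer`),
#'   `"band"` (`center`, `angle_deg`, `halfwidth`), or `"background"`
#'   (fills the abundance remaining after all other structures).
#' @param abundance Fractional abundance inside the geometry (0, 1].
#' @return A structure description list for [phantomSpec()].
#' @export
phantomStructure <- function(label, model, geometry, abundance = 1) {
  stopifnot(is(model, "SpectralModel"), abundance > 0, abundance <= 1)
  list(label = label, model = model, geometry = geometry,
       abundance = abundance)
}

#' @param shape Integer `(rows, cols)`.
#' @param structures List of [phantomStructure()] descriptions.
#' @param counts_per_pixel_per_frame Expected total counts per pure
#'   pixel per frame.
#' @param n_frames Accumulated frames.
#' @param seed RNG seed (fully determines the rendered cube).
#' @param energy [EnergyAxis-class]; default 250 channels of 80 eV
#'   (0-20 keV).
#' @param pixel_size_nm Pixel size in nm.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(shape, structures, counts_per_pixel_per_frame = 250,
                        n_frames = 20, seed = 1,
                        energy = EnergyAxis(40, 80, 250),
                        pixel_size_nm = 8) {
  new("PhantomSpec", shape = as.integer(shape), structures = structures,
      counts_per_pixel_per_frame = as.numeric(counts_per_pixel_per_frame),
      n_frames = as.integer(n_frames), seed = as.integer(seed),
      energy = energy, pixel_size_nm = as.numeric(pixel_size_nm))
}

#' Ground truth accompanying a rendered phantom
#'
#' @slot abundances Array `[row, col, K]` of ground-truth fractional
#'   abundances (sum <= 1 per pixel; background absorbs the remainder).
#' @slot labels Structure labels (length K).
#' @slot class_map Integer matrix of per-pixel argmax class (1..K).
#' @slot endmembers K x n_channels matrix: expected counts of a pure
#'   pixel of each class over the full frame accumulation.
#' @export
setClass("GroundTruth",
  representation(abundances = "array", labels = "character",
                 class_map = "matrix", endmembers = "matrix"))

#' Ground-truth binary mask of one phantom class
#' @param gt A [GroundTruth-class].
#' @param label Class label.
#' @param threshold Minimum abundance counted as membership (default 0.5).
#' @return Logical matrix.
#' @export
classMask <- function(gt, label, threshold = 0.5) {
  k <- match(label, gt@labels)
  if (is.na(k)) stop("unknown class label: ", label)
  gt@abundances[, , k] >= threshold
}

setMethod("show", "GroundTruth", function(object) {
  d <- dim(object@abundances)
  cat(sprintf("GroundTruth: %d x %d px, %d classes (%s)\n", d[1], d[2], d[3],
              paste(object@labels, collapse = ", ")))
})

# rasterize one geometric primitive to a logical mask
.rasterize <- function(prim, shape) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  switch(prim$type,
    disk = (r - prim$center[1])^2 + (c_ - prim$center[2])^2 <=
      prim$radius^2,
    ellipse = ((r - prim$center[1]) / prim$semi_axes[1])^2 +
      ((c_ - prim$center[2]) / prim$semi_axes[2])^2 <= 1,
    annulus = {
      d2 <- (r - prim$center[1])^2 + (c_ - prim$center[2])^2
      d2 > prim$r_inner^2 & d2 <= prim$r_outer^2
    },
    band = {
      th <- prim$angle_deg * pi / 180
      abs(cos(th) * (r - prim$center[1]) + sin(th) * (c_ - prim$center[2])) <=
        prim$halfwidth
    },
    stop("unknown geometry type: ", prim$type))
}

# ground-truth abundance array for a phantom spec
.groundTruthAbundances <- function(spec) {
  K <- length(spec@structures)
  A <- array(0, dim = c(spec@shape[1], spec@shape[2], K))
  bg <- integer(0)
  for (k in seq_len(K)) {
    st <- spec@structures[[k]]
    if (length(st$geometry) == 1 &&
        identical(st$geometry[[1]]$type, "background")) {
      bg <- c(bg, k)
      next
    }
    mask <- Reduce(`|`, lapply(st$geometry, .rasterize, shape = spec@shape))
    A[, , k] <- st$abundance * mask
  }
  tot <- apply(A, c(1, 2), sum)
  if (any(tot > 1 + 1e-9))
    stop("overlapping structures: per-pixel abundance exceeds 1 ",
         "(max ", format(max(tot)), ")")
  for (k in bg) A[, , k] <- pmax(1 - tot, 0)
  A
}

#' Render a phantom to a hyperspectral cube plus ground truth
#'
#' Expected counts follow the linear mixing model: for pixel p and
#' channel c, `lambda(p, c) = n_frames * cppf * sum_k A_k(p) * ehat_k(c)`
#' where `ehat_k` is the class spectrum normalised to unit sum and
#' `cppf` the expected counts per pure pixel per frame. With
#' `noiseless = FALSE` each frame is an independent Poisson draw (frame
#' j reproducible from `(seed, j)`) and frames are summed; with
#' `noiseless = TRUE` the expectation itself is returned.
#'
#' @param spec A [PhantomSpec-class].
#' @param noiseless Return expected values instead of Poisson draws.
#' @param n_frames Override the spec's frame count (optional).
#' @return List with elements `cube` ([HyperspectralCube-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
renderPhantom <- function(spec, noiseless = FALSE, n_frames = spec@n_frames) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  A <- .groundTruthAbundances(spec)
  K <- length(spec@structures)
  E <- t(vapply(spec@structures,
                function(st) expectedSpectrum(st$model, spec@energy),
                numeric(spec@energy@n_channels)))
  rs <- rowSums(E)
  if (any(rs <= 0)) stop("every structure needs a nonzero expected spectrum")
  Ehat <- E / rs
  d <- c(spec@shape, spec@energy@n_channels)
  Aflat <- matrix(A, d[1] * d[2], K)
  lam1 <- spec@counts_per_pixel_per_frame * (Aflat %*% Ehat)  # per frame
  if (noiseless) {
    counts <- array(n_frames * lam1, dim = d)
  } else {
    acc <- integer(length(lam1))
    for (j in seq_len(n_frames))
      acc <- acc + withSeed(.frameSeed(spec@seed, j),
                            rpois(length(lam1), lam1))
    counts <- array(acc, dim = d)  # raw counts stay integer
  }
  cube <- HyperspectralCube(counts, spec@energy,
                            pixel_size_nm = spec@pixel_size_nm,
                            n_frames = n_frames, dwell_us = 100)
  labels <- vapply(spec@structures, `[[`, "", "label")
  cm <- matrix(max.col(Aflat, ties.method = "first"), d[1], d[2])
  truth <- new("GroundTruth", abundances = A, labels = labels,
               class_map = cm,
               endmembers = n_frames * spec@counts_per_pixel_per_frame * Ehat)
  list(cube = cube, truth = truth)
}

# per-frame seed derived from (seed, frame); kept below 2^31
.frameSeed <- function(seed, j) {
  (as.double(seed) * 48271 + j * 9973) %% 2147483647
}

#' Render cumulative frame accumulations of a phantom
#'
#' Draws `k` independent Poisson frames (frame j reproducible from
#' `(seed, j)`, identical to the frames [renderPhantom()] sums) and
#' returns the cumulative sums: element j is the cube accumulated over
#' frames 1..j.
#'
#' @param spec A [PhantomSpec-class].
#' @param k Number of frames (>= 1).
#' @return List of `k` [HyperspectralCube-class] objects plus the
#'   [GroundTruth-class] as attribute `"truth"`.
#' @export
renderFrames <- function(spec, k) {
  stopifnot(is(spec, "PhantomSpec"))
  k <- as.integer(k)
  if (k < 1L) stop("frame count k must be >= 1")
  A <- .groundTruthAbundances(spec)
  K <- length(spec@structures)
  E <- t(vapply(spec@structures,
                function(st) expectedSpectrum(st$model, spec@energy),
                numeric(spec@energy@n_channels)))
  Ehat <- E / rowSums(E)
  d <- c(spec@shape, spec@energy@n_channels)
  lam1 <- spec@counts_per_pixel_per_frame *
    (matrix(A, d[1] * d[2], K) %*% Ehat)
  out <- vector("list", k)
  acc <- integer(length(lam1))
  for (j in seq_len(k)) {
    acc <- acc + withSeed(.frameSeed(spec@seed, j),
                          rpois(length(lam1), lam1))
    out[[j]] <- HyperspectralCube(array(acc, dim = d), spec@energy,
                                  pixel_size_nm = spec@pixel_size_nm,
                                  n_frames = j, dwell_us = 100)
  }
  labels <- vapply(spec@structures, `[[`, "", "label")
  truth <- new("GroundTruth", abundances = A, labels = labels,
               class_map = matrix(max.col(matrix(A, d[1] * d[2], K),
                                          ties.method = "first"),
                                  d[1], d[2]),
               endmembers = k * spec@counts_per_pixel_per_frame * Ehat)
  attr(out, "truth") <- truth
  out
}

# ---------------------------------------------------------------------------
# Canned spectral models and phantoms
# ---------------------------------------------------------------------------

# Characteristic line energies (eV) used by the canned models.
.lineEv <- c(C_Ka = 277, N_Ka = 392, O_Ka = 525, Fe_La = 705, Os_Ma = 1914,
             P_Ka = 2013, S_Ka = 2307, Fe_Ka = 6404, Cu_Ka = 8046,
             Os_La = 8911)

.lineSet <- function(amps, width_ev = 60) {
  data.frame(energy_ev = unname(.lineEv[names(amps)]),
             width_ev = width_ev, amplitude = unname(amps))
}

#' Canned per-structure spectral models
#'
#' Emulate the elemental signatures of stained tissue: a carbon-rich
#' background, protein-packed granules high in N and S, nucleic acids
#' high in P and N, osmium/iron-rich membranes. Line positions follow
#' the elements' characteristic energies; widths model detector
#' resolution (sigma = 60 eV); a decaying continuum underlies all
#' classes.
#'
#' @return Named list of [SpectralModel-class] objects.
#' @export
cannedSpectralModels <- function() {
  list(
    background = spectralModel(
      .lineSet(c(C_Ka = 60, O_Ka = 8, Cu_Ka = 4)),
      continuum_scale = 0.004, continuum_decay_ev = 4000),
    insulin = spectralModel(
      .lineSet(c(C_Ka = 25, N_Ka = 22, S_Ka = 20, P_Ka = 4, O_Ka = 6)),
      continuum_scale = 0.003, continuum_decay_ev = 4000),
    glucagon = spectralModel(
      .lineSet(c(C_Ka = 25, N_Ka = 28, S_Ka = 6, P_Ka = 8, O_Ka = 8)),
      continuum_scale = 0.003, continuum_decay_ev = 4000),
    pp_ghrelin = spectralModel(
      .lineSet(c(C_Ka = 25, N_Ka = 14, S_Ka = 12, P_Ka = 16, O_Ka = 6)),
      continuum_scale = 0.003, continuum_decay_ev = 4000),
    exocrine = spectralModel(
      .lineSet(c(C_Ka = 30, N_Ka = 24, S_Ka = 4, P_Ka = 2, O_Ka = 12)),
      continuum_scale = 0.003, continuum_decay_ev = 4000),
    nucleic_acids = spectralModel(
      .lineSet(c(C_Ka = 20, N_Ka = 18, P_Ka = 24, O_Ka = 12, Fe_La = 2)),
      continuum_scale = 0.003, continuum_decay_ev = 4000),
    membranes = spectralModel(
      .lineSet(c(C_Ka = 18, Os_Ma = 24, Os_La = 10, Fe_Ka = 10, Fe_La = 6)),
      continuum_scale = 0.006, continuum_decay_ev = 5000))
}

#' Default five-structure phantom
#'
#' A desk-scale scene echoing an islet of Langerhans field: three
#' endocrine granule populations (disks), exocrine granules (disks), a
#' nucleus standing in for nucleic acids (ellipse), all over a diffuse
#' carbon-rich background. Pixels inside structures are pure (abundance
#' 1), so ground-truth endmembers and class masks are exact.
#'
#' @param rows,cols Spatial shape (default 128 x 128).
#' @param counts_per_pixel_per_frame Expected counts per pure pixel per
#'   frame (default 250; with the default 20 frames, 5000 expected
#'   counts per pixel).
#' @param n_frames Accumulated frames (default 20).
#' @param seed RNG seed.
#' @param energy Energy axis (default 250 channels of 80 eV).
#' @return A [PhantomSpec-class].
#' @export
defaultPhantom <- function(rows = 128, cols = 128,
                           counts_per_pixel_per_frame = 250,
                           n_frames = 20, seed = 1,
                           energy = EnergyAxis(40, 80, 250)) {
  m <- cannedSpectralModels()
  s <- function(...) list(...)
  r <- rows / 128; c_ <- cols / 128  # scale placements with the canvas
  disk <- function(rr, cc, rad)
    s(type = "disk", center = c(rr * r, cc * c_), radius = rad * min(r, c_))
  structures <- list(
    phantomStructure("insulin", m$insulin,
      list(disk(24, 24, 11), disk(52, 18, 9), disk(30, 56, 8))),
    phantomStructure("glucagon", m$glucagon,
      list(disk(100, 28, 10), disk(112, 58, 8))),
    phantomStructure("pp_ghrelin", m$pp_ghrelin,
      list(disk(24, 100, 9), disk(52, 112, 8))),
    phantomStructure("exocrine", m$exocrine,
      list(disk(104, 104, 12), disk(78, 116, 7))),
    phantomStructure("nucleic_acids", m$nucleic_acids,
      list(s(type = "ellipse", center = c(68 * r, 68 * c_),
             semi_axes = c(16 * r, 12 * c_)))),
    phantomStructure("background", m$background,
      list(s(type = "background"))))
  phantomSpec(c(rows, cols), structures,
              counts_per_pixel_per_frame = counts_per_pixel_per_frame,
              n_frames = n_frames, seed = seed, energy = energy)
}

#' Four-class phantom for endmember / abundance recovery studies
#'
#' Two granule populations (disks), a nucleus (ellipse) and the diffuse
#' background: four spectrally distinct classes, every pixel pure, so
#' recovered endmembers and abundances can be scored exactly.
#'
#' @inheritParams defaultPhantom
#' @return A [PhantomSpec-class].
#' @export
fourClassPhantom <- function(rows = 96, cols = 96,
                             counts_per_pixel_per_frame = 250,
                             n_frames = 20, seed = 1,
                             energy = EnergyAxis(40, 80, 250)) {
  m <- cannedSpectralModels()
  s <- function(...) list(...)
  r <- rows / 96; c_ <- cols / 96
  disk <- function(rr, cc, rad)
    s(type = "disk", center = c(rr * r, cc * c_), radius = rad * min(r, c_))
  structures <- list(
    phantomStructure("insulin", m$insulin,
      list(disk(20, 20, 10), disk(44, 14, 8), disk(20, 48, 7))),
    phantomStructure("nucleic_acids", m$nucleic_acids,
      list(s(type = "ellipse", center = c(60 * r, 60 * c_),
             semi_axes = c(14 * r, 11 * c_)))),
    phantomStructure("membranes", m$membranes,
      list(disk(80, 20, 9), disk(20, 80, 8))),
    phantomStructure("background", m$background,
      list(s(type = "background"))))
  phantomSpec(c(rows, cols), structures,
              counts_per_pixel_per_frame = counts_per_pixel_per_frame,
              n_frames = n_frames, seed = seed, energy = energy)
}

#' Serialize / restore a phantom spec as plain-text YAML
#'
#' @param spec A [PhantomSpec-class].
#' @param path Output (input) path.
#' @return `writePhantomSpec` invisibly returns `path`;
#'   `readPhantomSpec` a [PhantomSpec-class].
#' @export
writePhantomSpec <- function(spec, path) {
  st <- lapply(spec@structures, function(s) list(
    label = s$label, abundance = s$abundance, geometry = s$geometry,
    model = list(lines = as.list(s$model@lines),
                 continuum_scale = s$model@continuum_scale,
                 continuum_decay_ev = s$model@continuum_decay_ev)))
  yaml::write_yaml(list(
    shape = as.integer(spec@shape),
    counts_per_pixel_per_frame = spec@counts_per_pixel_per_frame,
    n_frames = spec@n_frames, seed = spec@seed,
    pixel_size_nm = spec@pixel_size_nm,
    energy = list(offset_ev = spec@energy@offset_ev,
                  bin_width_ev = spec@energy@bin_width_ev,
                  n_channels = spec@energy@n_channels),
    structures = st), path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  structures <- lapply(y$structures, function(s) {
    lines <- as.data.frame(s$model$lines)
    geom <- lapply(s$geometry, function(g) {
      for (f in c("center", "semi_axes")) if (!is.null(g[[f]]))
        g[[f]] <- as.numeric(g[[f]])
      g
    })
    phantomStructure(s$label,
      spectralModel(lines, s$model$continuum_scale,
                    s$model$continuum_decay_ev),
      geom, s$abundance)
  })
  phantomSpec(y$shape, structures,
              counts_per_pixel_per_frame = y$counts_per_pixel_per_frame,
              n_frames = y$n_frames, seed = y$seed,
              energy = EnergyAxis(y$energy$offset_ev, y$energy$bin_width_ev,
                                  y$energy$n_channels),
              pixel_size_nm = y$pixel_size_nm)
}
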