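# Frame-accumulation convergence: intra-class relative spectral
# distance and intra/inter distance ratio as a function of accumulated
# frame count, to determine the minimum frames needed for stable
# class spectra.

#' Relative intra-class spectral distance
#'
#' Mean Euclidean distance of class members from the class mean,
#' divided by the norm of the class mean ("relative" convention,
#' tagged in downstream outputs). Spectra are first divided by the
#' frame count so counts are comparable across accumulations; the
#' statistic itself is invariant to that (and any) global rescaling.
#'
#' @param spectra Numeric `[member, channel]` matrix (>= 2 members).
#' @param k Frame count the spectra were accumulated over (default 1).
#' @return Nonnegative scalar; 0 when all members are identical.
#' @export
intraClassDistance <- function(spectra, k = 1) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2)
    stop("intra-class distance needs at least 2 member spectra")
  s <- spectra / k
  mu <- colMeans(s)
  nmu <- sqrt(sum(mu^2))
  if (nmu == 0) return(0)
  mean(sqrt(rowSums(sweep(s, 2, mu)^2))) / nmu
}

#' Relative inter-class spectral distance
#'
#' Euclidean distance between two class means divided by the norm of
#' their midpoint; symmetric in its arguments.
#'
#' @param mu_a,mu_b Class mean spectra (numeric vectors).
#' @param k Frame count (default 1).
#' @return Nonnegative scalar.
#' @export
interClassDistance <- function(mu_a, mu_b, k = 1) {
  a <- mu_a / k; b <- mu_b / k
  mid <- (a + b) / 2
  nmid <- sqrt(sum(mid^2))
  if (nmid == 0) return(0)
  sqrt(sum((a - b)^2)) / nmid
}

#' Distance curves versus frame accumulation
#'
#' Renders cumulative frame accumulations of a phantom (or consumes a
#' caller-provided list of cubes), samples per-class pixel spectra from
#' the ground-truth class map, and evaluates the intra-class relative
#' distance and the intra/inter ratio at each requested frame count.
#'
#' @param spec A [PhantomSpec-class] (frames drawn with
#'   [renderFrames()]).
#' @param frame_counts Strictly increasing frame counts to evaluate
#'   (default `2^(0:6)`).
#' @param pixels_per_class Pixels sampled per class (default 100).
#' @param classes Optional subset of class labels (default: all classes
#'   with enough pure pixels).
#' @param seed Seed for the pixel sample.
#' @return A [DistanceCurves-class].
#' @export
distanceVsFrames <- function(spec, frame_counts = 2^(0:6),
                             pixels_per_class = 100, classes = NULL,
                             seed = 1) {
  stopifnot(is(spec, "PhantomSpec"))
  frame_counts <- sort(unique(as.integer(frame_counts)))
  if (any(frame_counts < 1)) stop("frame counts must be >= 1")
  cubes <- renderFrames(spec, max(frame_counts))
  truth <- attr(cubes, "truth")
  d <- dim(truth@abundances)
  if (is.null(classes)) classes <- truth@labels
  # pure pixels per class, subsampled for tractability
  picks <- list()
  for (l in classes) {
    k <- match(l, truth@labels)
    idx <- which(truth@abundances[, , k] >= 0.999)
    if (length(idx) < 2) next
    if (length(idx) > pixels_per_class)
      idx <- withSeed(seed + k, sample(idx, pixels_per_class))
    picks[[l]] <- idx
  }
  if (length(picks) < 2)
    stop("need at least 2 classes with >= 2 pure pixels each")
  classes <- names(picks)
  nC <- length(classes)
  intra <- matrix(NA_real_, nC, length(frame_counts),
                  dimnames = list(classes, frame_counts))
  pairs <- utils::combn(nC, 2)
  ratio <- matrix(NA_real_, ncol(pairs), length(frame_counts),
                  dimnames = list(apply(pairs, 2, function(p)
                    paste(classes[p], collapse = "|")), frame_counts))
  for (j in seq_along(frame_counts)) {
    k <- frame_counts[j]
    flat <- matrix(cubes[[k]]@counts, d[1] * d[2],
                   dim(cubes[[k]]@counts)[3])
    mus <- list()
    for (ci in seq_len(nC)) {
      S <- flat[picks[[ci]], , drop = FALSE]
      intra[ci, j] <- intraClassDistance(S, k = k)
      mus[[ci]] <- colMeans(S / k)
    }
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      inter <- interClassDistance(mus[[a]], mus[[b]])
      ratio[p, j] <- if (inter == 0) NA_real_ else
        mean(c(intra[a, j], intra[b, j])) / inter
    }
  }
  new("DistanceCurves", frame_counts = as.numeric(frame_counts),
      intra = intra, ratio = ratio,
      mean_ratio = colMeans(ratio, na.rm = TRUE),
      normalization = "distance / ||class mean|| (intra); ||mu_a - mu_b|| / ||midpoint|| (inter)")
}

#' Plateau frame count of a distance curve
#'
#' First frame count at which the relative change of the curve per
#' doubling drops below `tol` of the curve's initial value (a repo
#' convention for reading stabilisation off the curves).
#'
#' @param curves A [DistanceCurves-class].
#' @param tol Relative change threshold (default 0.05).
#' @return Named numeric vector: plateau frame count per class
#'   (NA when the curve never stabilises over the evaluated range).
#' @export
plateauFrames <- function(curves, tol = 0.05) {
  fc <- curves@frame_counts
  out <- setNames(rep(NA_real_, nrow(curves@intra)),
                  rownames(curves@intra))
  for (ci in seq_len(nrow(curves@intra))) {
    v <- curves@intra[ci, ]
    ref <- v[1]
    if (!is.finite(ref) || ref == 0) next
    for (j in 2:length(fc)) {
      if (abs(v[j] - v[j - 1]) / ref < tol) {
        out[ci] <- fc[j]
        break
      }
    }
  }
  out
}

#' Log-log slope of intra-class distance versus frame count
#'
#' Under pure Poisson counting noise the intra-class distance scales as
#' `1/sqrt(k)`, i.e. a log-log slope of -0.5.
#'
#' @param curves A [DistanceCurves-class].
#' @return Named numeric vector of per-class slopes.
#' @export
intraDistanceSlopes <- function(curves) {
  fc <- curves@frame_counts
  apply(curves@intra, 1, function(v) {
    ok <- is.finite(v) & v > 0
    if (sum(ok) < 2) return(NA_real_)
    unname(coef(lm(log(v[ok]) ~ log(fc[ok])))[2])
  })
}
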