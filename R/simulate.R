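# Synthetic-data generation: negative-binomial spectral-count matrices
# with planted differential effects, elliptical cell contours, and
# division timelines with prescribed durations. All generators are
# deterministic given their seed and leave the caller's RNG untouched.

#' Simulation settings for synthetic spectral-count data
#'
#' Defines the generative model for a 2-condition spectral-count
#' experiment. Per-protein baseline abundances \eqn{\lambda_i} are
#' log-normal; counts for protein i in replicate j are negative binomial
#' (Gamma-Poisson) with mean \eqn{\lambda_i \cdot 2^{\delta_i [mitosis]}
#' \cdot f_j} and a single global overdispersion \eqn{\phi}
#' (variance \eqn{\mu + \phi \mu^2}), where \eqn{f_j} is the replicate
#' depth factor and \eqn{\delta_i} the planted log2 effect of
#' differentially abundant (DA) proteins. A fraction of proteins is
#' condition-specific — structurally zero in interphase, emulating
#' nuclear proteins released into mitotic blebs after nuclear envelope
#' breakdown — and a fraction is flagged actin-annotated for curation
#' tests. Unique peptide counts are drawn as
#' `1 + Poisson(uniquePeptideRate * log10(lambda + 1))`, reflecting that
#' spectral counts scale with both abundance and protein size.
#'
#' @slot nProteins number of proteins.
#' @slot nReplicates replicates per condition (default 3).
#' @slot baselineLogMean,baselineLogSd meanlog/sdlog of the log-normal
#'   baseline abundance.
#' @slot dispersion global negative-binomial overdispersion
#'   \eqn{\phi > 0}; 0 gives Poisson counts.
#' @slot depthFactors positive depth factor per replicate, ordered
#'   interphase replicates then mitosis replicates.
#' @slot fractionDa fraction of proteins with a planted effect.
#' @slot effectLog2Mean,effectLog2Sd normal distribution of planted
#'   log2 effects \eqn{\delta_i} (positive = mitosis-enriched).
#' @slot fractionConditionSpecific fraction of mitosis-only proteins
#'   (structural zeros in interphase); `fractionDa +
#'   fractionConditionSpecific` must not exceed 1.
#' @slot fractionActinAnnotated fraction flagged actin-related.
#' @slot uniquePeptideRate rate scale for unique peptide counts.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
         representation(nProteins = "integer", nReplicates = "integer",
                        baselineLogMean = "numeric", baselineLogSd = "numeric",
                        dispersion = "numeric", depthFactors = "numeric",
                        fractionDa = "numeric", effectLog2Mean = "numeric",
                        effectLog2Sd = "numeric",
                        fractionConditionSpecific = "numeric",
                        fractionActinAnnotated = "numeric",
                        uniquePeptideRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (f in c("fractionDa", "fractionConditionSpecific",
              "fractionActinAnnotated")) {
    v <- slot(object, f)
    if (!is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", f))
  }
  if (object@fractionDa + object@fractionConditionSpecific > 1)
    msg <- c(msg, "fractionDa + fractionConditionSpecific must be <= 1")
  if (!is.finite(object@dispersion) || object@dispersion < 0)
    msg <- c(msg, "'dispersion' must be >= 0")
  if (any(!is.finite(object@depthFactors)) || any(object@depthFactors <= 0))
    msg <- c(msg, "'depthFactors' must all be > 0")
  if (length(object@depthFactors) != 2L * object@nReplicates)
    msg <- c(msg, sprintf(
      "'depthFactors' must have one entry per replicate (%d), got %d",
      2L * object@nReplicates, length(object@depthFactors)))
  if (object@nProteins < 1L) msg <- c(msg, "'nProteins' must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "'nReplicates' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#'
#' @details Defaults emulate the scale of a cortex-enriched bleb
#' experiment: 2000 proteins, 3 vs 3 replicates, a wide log-normal
#' abundance range (meanlog `log(20)`, sdlog 1.5), mild overdispersion
#' (0.1), run-to-run sequencing-depth variation of roughly ±20%, a fifth
#' of proteins differential with ~1.5 log2 effects, 15% mitosis-only
#' "nuclear" proteins and a quarter actin-annotated.
#'
#' @param nProteins,nReplicates,baselineLogMean,baselineLogSd,dispersion,depthFactors,fractionDa,effectLog2Mean,effectLog2Sd,fractionConditionSpecific,fractionActinAnnotated,uniquePeptideRate,seed
#'   see slot documentation.
#' @return A validated `SimulationConfig`.
#' @examples
#' cfg <- SimulationConfig(nProteins = 100, seed = 7)
#' sim <- simulateCounts(cfg)
#' sim$counts
#' head(sim$truth)
#' @export
SimulationConfig <- function(nProteins = 2000L,
                             nReplicates = 3L,
                             baselineLogMean = log(20),
                             baselineLogSd = 1.5,
                             dispersion = 0.1,
                             depthFactors = NULL,
                             fractionDa = 0.2,
                             effectLog2Mean = 1.5,
                             effectLog2Sd = 0.5,
                             fractionConditionSpecific = 0.15,
                             fractionActinAnnotated = 0.25,
                             uniquePeptideRate = 5,
                             seed = 1L) {
  checkScalar(nProteins, "nProteins", lower = 1, integer = TRUE)
  checkScalar(nReplicates, "nReplicates", lower = 1, integer = TRUE)
  checkScalar(baselineLogMean, "baselineLogMean")
  checkScalar(baselineLogSd, "baselineLogSd", lower = 0)
  checkScalar(dispersion, "dispersion", lower = 0)
  checkScalar(fractionDa, "fractionDa", lower = 0, upper = 1)
  checkScalar(effectLog2Mean, "effectLog2Mean")
  checkScalar(effectLog2Sd, "effectLog2Sd", lower = 0)
  checkScalar(fractionConditionSpecific, "fractionConditionSpecific",
              lower = 0, upper = 1)
  checkScalar(fractionActinAnnotated, "fractionActinAnnotated",
              lower = 0, upper = 1)
  checkScalar(uniquePeptideRate, "uniquePeptideRate", lower = 0,
              inclusive = FALSE, upper = Inf)
  checkScalar(seed, "seed", integer = TRUE)
  if (is.null(depthFactors)) {
    base <- c(1, 0.85, 1.2, 1.1, 0.9, 1.05)
    depthFactors <- rep_len(base, 2L * nReplicates)
  }
  if (any(!is.finite(depthFactors)))
    configError("'depthFactors' must be finite")
  obj <- tryCatch(new("SimulationConfig",
             nProteins = as.integer(nProteins),
             nReplicates = as.integer(nReplicates),
             baselineLogMean = baselineLogMean,
             baselineLogSd = baselineLogSd,
             dispersion = dispersion,
             depthFactors = as.numeric(depthFactors),
             fractionDa = fractionDa,
             effectLog2Mean = effectLog2Mean,
             effectLog2Sd = effectLog2Sd,
             fractionConditionSpecific = fractionConditionSpecific,
             fractionActinAnnotated = fractionActinAnnotated,
             uniquePeptideRate = uniquePeptideRate,
             seed = as.integer(seed)),
             error = function(e) configError(conditionMessage(e)))
  obj
}

#' @describeIn SimulationConfig-class compact display.
#' @param object a `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d proteins, %d vs %d replicates, dispersion %.3g,\n",
    "  fractionDa %.2f (delta ~ N(%.2f, %.2f)), condition-specific %.2f,\n",
    "  actin-annotated %.2f, seed %d\n"),
    object@nProteins, object@nReplicates, object@nReplicates,
    object@dispersion, object@fractionDa, object@effectLog2Mean,
    object@effectLog2Sd, object@fractionConditionSpecific,
    object@fractionActinAnnotated, object@seed))
})

#' Simulate a spectral-count experiment with known ground truth
#'
#' Draws a protein x replicate count matrix from the generative model
#' described in [SimulationConfig-class] and returns it together with
#' the planted truth labels, so downstream selection, testing and
#' ranking can be validated against a known answer.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with elements:
#' \describe{
#'   \item{`counts`}{a [SpectralCountSet-class] (`nProteins` rows,
#'     `2 * nReplicates` columns, interphase columns first).}
#'   \item{`truth`}{a `DataFrame` with per-protein `is_da`,
#'     `true_log2_effect` (0 for non-DA proteins),
#'     `is_condition_specific` and `is_actin_annotated`, plus the latent
#'     `baseline_mean`.}
#' }
#' @examples
#' sim <- simulateCounts(SimulationConfig(nProteins = 50, seed = 42))
#' table(sim$truth$is_da)
#' @export
simulateCounts <- function(config) {
  if (!is(config, "SimulationConfig"))
    configError("'config' must be a SimulationConfig")
  validObject(config)
  n <- config@nProteins
  nr <- config@nReplicates
  withSeed(config@seed, {
    lambda <- rlnorm(n, config@baselineLogMean, config@baselineLogSd)

    # protein status: DA, condition-specific (mitosis-only), or null
    u <- runif(n)
    is_da <- u < config@fractionDa
    is_cs <- !is_da &
      u < config@fractionDa + config@fractionConditionSpecific
    delta <- numeric(n)
    delta[is_da] <- rnorm(sum(is_da), config@effectLog2Mean,
                          config@effectLog2Sd)
    is_actin <- runif(n) < config@fractionActinAnnotated

    condition <- rep(CONDITIONS, each = nr)
    mu <- outer(lambda, config@depthFactors)
    mit <- condition == "mitosis"
    mu[, mit] <- mu[, mit] * 2^delta

    counts <- matrix(0L, n, 2L * nr)
    draw <- function(m) {
      if (config@dispersion == 0) rpois(length(m), m)
      else rnbinom(length(m), size = 1 / config@dispersion, mu = m)
    }
    counts[] <- draw(mu)
    counts[is_cs, !mit] <- 0L  # structural zeros in interphase

    upep <- 1L + rpois(n, config@uniquePeptideRate * log10(lambda + 1))

    acc <- sprintf("SYNP%05d", seq_len(n))
    sym <- sprintf("GENE%04d", seq_len(n))
    scs <- SpectralCountSet(
      matrix(as.integer(counts), n, 2L * nr, dimnames = list(acc, NULL)),
      condition = condition,
      geneSymbol = sym, uniquePeptides = upep)
    truth <- S4Vectors::DataFrame(
      is_da = is_da,
      true_log2_effect = delta,
      is_condition_specific = is_cs,
      is_actin_annotated = is_actin,
      baseline_mean = lambda,
      row.names = acc)
    list(counts = scs, truth = truth)
  })
}

#' Simulate an elliptical cell contour
#'
#' Generates a polygonal contour tracing an ellipse with the requested
#' major/minor axis ratio, optionally perturbed by radial Gaussian
#' noise, as a fixture for the shape metrics. With `noiseSd = 0` the
#' polygon is simple by construction.
#'
#' @param axisRatio major/minor axis ratio, >= 1.
#' @param nVertices number of vertices, >= 8.
#' @param noiseSd standard deviation (µm) of radial noise (default 0).
#' @param seed RNG seed (only consumed when `noiseSd > 0`).
#' @param minorAxisUm minor semi-axis in µm (default 10, a typical
#'   rounded HeLa cell radius).
#' @return A [CellContour-class].
#' @examples
#' circularity(simulateContour(1, nVertices = 512))
#' @export
simulateContour <- function(axisRatio, nVertices = 256L, noiseSd = 0,
                            seed = 1L, minorAxisUm = 10) {
  checkScalar(axisRatio, "axisRatio", lower = 1)
  checkScalar(nVertices, "nVertices", lower = 8, integer = TRUE)
  checkScalar(noiseSd, "noiseSd", lower = 0)
  checkScalar(minorAxisUm, "minorAxisUm", lower = 0, inclusive = FALSE,
              upper = Inf)
  theta <- 2 * pi * (seq_len(nVertices) - 1L) / nVertices
  p <- cbind(axisRatio * minorAxisUm * cos(theta),
             minorAxisUm * sin(theta))
  if (noiseSd > 0) {
    eps <- withSeed(seed, rnorm(nVertices, 0, noiseSd))
    r <- sqrt(rowSums(p^2))
    p <- p * (1 + eps / r)
  }
  CellContour(p)
}

#' Simulate an annotated division timeline
#'
#' Builds a [DivisionEvents-class] whose landmark frames realise the
#' requested rounding and ingression durations at the given frame
#' interval.
#'
#' @param roundingDurationFrames frames from rounding onset to the first
#'   fully round frame (>= 0).
#' @param ingressionDurationFrames frames from the end of metaphase to
#'   the end of furrow ingression (>= 0).
#' @param frameIntervalMin acquisition interval in minutes (default 2).
#' @param onsetFrame frame index of rounding onset (default 0).
#' @param metaphaseDurationFrames frames between rounding completion and
#'   the last metaphase frame (default 15, i.e. 30 min at 2 min/frame).
#' @return A [DivisionEvents-class].
#' @examples
#' ev <- simulateDivisionTimeline(5, 5, frameIntervalMin = 2)
#' roundingTime(ev)    # 10 min
#' ingressionTime(ev)  # 10 min
#' @export
simulateDivisionTimeline <- function(roundingDurationFrames,
                                     ingressionDurationFrames,
                                     frameIntervalMin = 2,
                                     onsetFrame = 0L,
                                     metaphaseDurationFrames = 15L) {
  checkScalar(roundingDurationFrames, "roundingDurationFrames",
              lower = 0, integer = TRUE)
  checkScalar(ingressionDurationFrames, "ingressionDurationFrames",
              lower = 0, integer = TRUE)
  checkScalar(metaphaseDurationFrames, "metaphaseDurationFrames",
              lower = 0, integer = TRUE)
  checkScalar(frameIntervalMin, "frameIntervalMin", lower = 0,
              inclusive = FALSE, upper = Inf)
  onset <- as.integer(onsetFrame)
  complete <- onset + as.integer(roundingDurationFrames)
  metaEnd <- complete + as.integer(metaphaseDurationFrames)
  DivisionEvents(onset, complete, metaEnd,
                 metaEnd + as.integer(ingressionDurationFrames),
                 frameIntervalMin)
}
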