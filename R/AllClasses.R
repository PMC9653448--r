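#' SweepSet: a current-clamp step-protocol recording
#'
#' Container for a set of voltage sweeps recorded from one cell under a
#' square-pulse current-step protocol.  All sweeps share a common time base;
#' each sweep has an injected current amplitude and a stimulus window.
#'
#' @slot dt sampling interval in ms.
#' @slot voltages numeric matrix, samples x sweeps, in mV; column names are
#'   sweep identifiers.
#' @slot protocol data.frame with columns \code{sweep_id}, \code{current_pA},
#'   \code{onset_ms}, \code{offset_ms}, one row per sweep in column order.
#'
#' @seealso [simulateSweepSet()], [extractFeatureTable()], [readSweepSet()]
#' @export
setClass("SweepSet",
  representation(dt = "numeric", voltages = "matrix", protocol = "data.frame"))

setValidity("SweepSet", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0) {
    msg <- c(msg, "sampling interval 'dt' must be a single positive number")
  }
  p <- object@protocol
  need <- c("sweep_id", "current_pA", "onset_ms", "offset_ms")
  if (!all(need %in% names(p))) {
    msg <- c(msg, paste("protocol must have columns:",
                        paste(need, collapse = ", ")))
  } else {
    if (nrow(p) != ncol(object@voltages)) {
      msg <- c(msg, "protocol must have one row per sweep column")
    }
    if (!identical(as.character(p$sweep_id), colnames(object@voltages))) {
      msg <- c(msg, "protocol sweep_id must match voltage column names")
    }
    tmax <- (nrow(object@voltages) - 1L) * object@dt
    if (nrow(p) > 0 && any(!(p$onset_ms < p$offset_ms & p$offset_ms <= tmax))) {
      msg <- c(msg, "each sweep needs onset < offset <= trace end")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SweepSet construct a SweepSet
#' @param voltages,protocol,dt see slots.
#' @export
SweepSet <- function(voltages, protocol, dt) {
  voltages <- as.matrix(voltages)
  if (is.null(colnames(voltages))) {
    colnames(voltages) <- paste0("sweep", seq_len(ncol(voltages)))
  }
  protocol$sweep_id <- as.character(protocol$sweep_id)
  new("SweepSet", dt = as.numeric(dt), voltages = voltages,
      protocol = as.data.frame(protocol))
}

#' @describeIn SweepSet sampling interval in ms
#' @param x a SweepSet.
#' @export
samplingInterval <- function(x) x@dt

#' @describeIn SweepSet sample times in ms
#' @export
sweepTimes <- function(x) (seq_len(nrow(x@voltages)) - 1L) * x@dt

#' @describeIn SweepSet voltage matrix (samples x sweeps, mV)
#' @export
sweepVoltages <- function(x) x@voltages

#' @describeIn SweepSet protocol table
#' @export
sweepProtocol <- function(x) x@protocol

setMethod("show", "SweepSet", function(object) {
  p <- object@protocol
  cat("SweepSet:", ncol(object@voltages), "sweeps x",
      nrow(object@voltages), "samples @", object@dt, "ms\n")
  cat("  currents (pA):", paste(signif(p$current_pA, 4), collapse = ", "),
      "\n")
  cat("  stimulus:", p$onset_ms[1], "-", p$offset_ms[1], "ms\n")
})

#' ClassProfile: collapsed class-level z-score profiles for one species
#'
#' Gene x cell-class matrix of z-scores collapsed by the two-stage rule:
#' a within-subclass statistic (mean by default, median optionally) followed
#' by an unweighted mean over the subclasses of each class.  Equal subclass
#' weighting deliberately ignores subclass abundance so that large
#' populations do not dominate a class profile.
#'
#' @slot species species label.
#' @slot profile numeric matrix, genes x classes.
#' @slot nSubclasses named integer vector: subclasses per class.
#' @slot collapse within-subclass statistic used ("mean" or "median").
#'
#' @seealso [collapseToClassProfile()], [genesetCorrelations()]
#' @export
setClass("ClassProfile",
  representation(species = "character", profile = "matrix",
                 nSubclasses = "integer", collapse = "character"))

setValidity("ClassProfile", function(object) {
  msg <- character()
  if (length(object@species) != 1L) msg <- c(msg, "species must be length 1")
  if (is.null(rownames(object@profile)) || is.null(colnames(object@profile))) {
    msg <- c(msg, "profile must have gene rownames and class colnames")
  }
  if (!identical(sort(names(object@nSubclasses)),
                 sort(colnames(object@profile)))) {
    msg <- c(msg, "nSubclasses must be named by the profile classes")
  }
  if (any(object@nSubclasses < 1L)) {
    msg <- c(msg, "every class must contain at least one subclass")
  }
  if (!object@collapse %in% c("mean", "median")) {
    msg <- c(msg, "collapse must be 'mean' or 'median'")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ClassProfile the gene x class matrix
#' @param x a ClassProfile.
#' @export
profileMatrix <- function(x) x@profile

#' @describeIn ClassProfile species label
#' @export
profileSpecies <- function(x) x@species

setMethod("show", "ClassProfile", function(object) {
  cat("ClassProfile [", object@species, "]: ", nrow(object@profile),
      " genes x ", ncol(object@profile), " classes (",
      paste(colnames(object@profile), collapse = ", "), "); collapse = ",
      object@collapse, "\n", sep = "")
})

#' OverlapMatrix: cross-species co-clustering overlap
#'
#' Rows are native clusters of species A, columns native clusters of species
#' B.  Entry (a, b) is the sum over joint (integrated) clusters of the
#' minimum of the two clusters' joint-membership proportions, i.e.
#' 1 minus the total-variation distance between their joint-cluster
#' proportion vectors.  Values lie in [0, 1]; 1 means identical proportion
#' vectors, 0 means disjoint joint-cluster support.
#'
#' @slot overlap numeric matrix with cluster dimnames.
#' @slot speciesA,speciesB the two species labels.
#'
#' @seealso [clusterOverlap()], [homologyPipeline()]
#' @export
setClass("OverlapMatrix",
  representation(overlap = "matrix", speciesA = "character",
                 speciesB = "character"))

setValidity("OverlapMatrix", function(object) {
  msg <- character()
  o <- object@overlap
  if (length(o) && (min(o) < -1e-12 || max(o) > 1 + 1e-12)) {
    msg <- c(msg, "overlap entries must lie in [0, 1]")
  }
  if (is.null(rownames(o)) || is.null(colnames(o))) {
    msg <- c(msg, "overlap must carry cluster dimnames")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn OverlapMatrix coerce to a plain matrix
#' @param x an OverlapMatrix.
#' @export
setMethod("as.matrix", "OverlapMatrix", function(x) x@overlap)

setMethod("show", "OverlapMatrix", function(object) {
  cat("OverlapMatrix: ", nrow(object@overlap), " ", object@speciesA,
      " clusters x ", ncol(object@overlap), " ", object@speciesB,
      " clusters; range [", signif(min(object@overlap), 3), ", ",
      signif(max(object@overlap), 3), "]\n", sep = "")
})

#' EphysFeatures: the extracted feature record for one cell
#'
#' Named vector of the fourteen intrinsic electrophysiological features with
#' per-feature availability flags.  A feature that cannot be computed from
#' the supplied sweeps (e.g. rheobase when no sweep spikes) is flagged
#' unavailable and set to NA, never silently zero.
#'
#' @slot values named numeric vector of feature values.
#' @slot available named logical vector, same names as \code{values}.
#' @slot details list of per-feature diagnostics (sweep used, fit info).
#'
#' @seealso [extractFeatureTable()]
#' @export
setClass("EphysFeatures",
  representation(values = "numeric", available = "logical",
                 details = "list"))

.EPHYS_FEATURES <- c(
  "rmp_mV", "ap_threshold_mV", "ap_amplitude_mV", "ap_width_ms",
  "ap_rising_time_ms", "ap_decay_time_ms", "ahp_mV", "rheobase_pA",
  "spike_delay_ms", "sag_ratio", "rebound_mV", "tau_ms",
  "adaptive_index", "input_resistance_MOhm")

setValidity("EphysFeatures", function(object) {
  msg <- character()
  if (!identical(names(object@values), .EPHYS_FEATURES)) {
    msg <- c(msg, "values must be named by the 14 canonical features")
  }
  if (!identical(names(object@available), .EPHYS_FEATURES)) {
    msg <- c(msg, "available must be named by the 14 canonical features")
  }
  if (any(!object@available & !is.na(object@values))) {
    # an unavailable feature must not carry a value
    msg <- c(msg, "unavailable features must be NA")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn EphysFeatures named feature values (NA where unavailable)
#' @param x an EphysFeatures object.
#' @export
featureValues <- function(x) x@values

#' @describeIn EphysFeatures named availability flags
#' @export
featureAvailable <- function(x) x@available

#' @describeIn EphysFeatures per-feature diagnostics
#' @export
featureDetails <- function(x) x@details

setMethod("show", "EphysFeatures", function(object) {
  cat("EphysFeatures:", sum(object@available), "of",
      length(object@values), "features available\n")
  v <- object@values
  for (nm in names(v)) {
    cat(sprintf("  %-22s %s\n", nm,
                if (object@available[[nm]]) signif(v[[nm]], 5) else "NA"))
  }
})
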