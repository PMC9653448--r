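#' @import methods
#' @importFrom stats rnorm rnbinom rlnorm median var sd setNames aggregate
#'   complete.cases pnorm pt lm coef kmeans prcomp optimize uniroot approx
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

# Deterministic child seed from a parent seed and a string tag.  Keeps every
# generator a pure function of (config, seed) while letting independent
# components (per-species draws, per-cluster subsampling) consume independent
# streams.  The hash is a plain polynomial string hash mod a Mersenne prime so
# it is identical across platforms.
.childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  # keep every product below 2^53 so the arithmetic stays exact in doubles
  h <- (h %% 1048573) * 2038074743 + (h %% 7919) * 104729
  as.integer((abs(seed) + h) %% 2147483647) # < 2^31
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

.assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop("'", name, "' must be TRUE or FALSE", call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

# Extract a genes x cells matrix from either a matrix-like object or a
# SummarizedExperiment assay.
.getAssay <- function(x, assay, what) {
  if (is(x, "SummarizedExperiment")) {
    if (!assay %in% SummarizedExperiment::assayNames(x)) {
      stop(what, " requires assay '", assay, "'; found: ",
           paste(SummarizedExperiment::assayNames(x), collapse = ", "),
           call. = FALSE)
    }
    SummarizedExperiment::assay(x, assay)
  } else {
    x
  }
}
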