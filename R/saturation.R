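## Per-class Poisson recovery model.
##
## The screen literature argues saturation qualitatively ("nearly every
## accessible PTC class was seen").  The model here makes that argument
## quantitative, and is this package's own formalization, labelled as such
## in all reports: each accessible mutation class i is recovered
## X_i ~ Poisson(lambda * w_i) times, independently.  Then
## P(class i missed) = exp(-lambda * w_i), the expected number of unseen
## classes is sum_i exp(-lambda * w_i), and the probability that every
## class was seen is prod_i (1 - exp(-lambda * w_i)).

#' Maximum-likelihood Poisson recovery rate
#'
#' With `includeZeros = TRUE` the multiplicity vector is taken to
#' enumerate all classes (zeros are real observations) and the MLE is the
#' weighted sample mean `sum(x) / sum(w)`.  With `includeZeros = FALSE`
#' only positive counts are informative (classes never seen are invisible)
#' and the zero-truncated Poisson MLE is used: the rate solves
#' `lambda / (1 - exp(-lambda)) = mean(positive counts)` in the
#' unweighted case, found by bracketed root-finding on `[1e-8, 50]` to
#' `|f| < 1e-10`.  If the mean positive count is at the truncated
#' distribution's lower limit of 1, the MLE is the boundary `lambda = 0`.
#'
#' @param multiplicities nonnegative integer vector of per-class recovery
#'   counts.
#' @param includeZeros logical; are zero counts observed classes?
#' @param weights optional positive per-class rate multipliers (same
#'   length as `multiplicities`), e.g. the number of distinct nucleotide
#'   routes to each class.
#' @return the estimated rate `lambda` (numeric scalar).
#' @examples
#' fitRate(c(1, 1, 1, 1), includeZeros = TRUE)   # 1
#' @export
fitRate <- function(multiplicities, includeZeros = FALSE, weights = NULL) {
  x <- as.numeric(multiplicities)
  if (length(x) == 0L || any(is.na(x)) || any(x < 0))
    stop("multiplicities must be nonnegative counts")
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  if (length(w) != length(x) || any(w <= 0))
    stop("weights must be positive and match multiplicities in length")
  if (includeZeros) return(sum(x) / sum(w))
  pos <- x > 0
  if (!any(pos))
    stop("undefined fit: no positive counts and includeZeros = FALSE")
  x <- x[pos]; w <- w[pos]
  ## zero-truncated score: f(lambda) = sum(x)/lambda - sum(w/(1-exp(-lambda*w)))
  f <- function(l) sum(x) / l - sum(w / (1 - exp(-l * w)))
  lo <- 1e-8; hi <- 50
  if (f(lo) <= 0) return(0)     # mean at/below truncated lower limit
  if (f(hi) > 0)
    stop("recovery rate exceeds search bracket upper bound 50")
  r <- uniroot(f, c(lo, hi), tol = 1e-12)
  stopifnot(abs(f(r$root)) < 1e-10)
  r$root
}

#' Probability that a mutation class was never recovered
#'
#' Under the Poisson recovery model, `exp(-lambda * weight)`.
#'
#' @param lambda nonnegative recovery rate.
#' @param weight per-class rate multiplier (default 1).
#' @return miss probability in `[0, 1]` (vectorised over both arguments).
#' @export
probClassMissed <- function(lambda, weight = 1) {
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  exp(-lambda * weight)
}

#' Construct a fitted screen recovery model
#'
#' @param multiplicities named (or unnamed) nonnegative integer vector of
#'   per-class recovery counts, covering all `n` accessible classes.
#' @param weights optional per-class rate multipliers.
#' @param lambda optional fixed rate; when `NULL` (default) the rate is
#'   fitted with [fitRate()].
#' @param includeZeros passed to [fitRate()]; `TRUE` (default) treats the
#'   vector as a complete enumeration of classes.
#' @return a [ScreenModel-class].
#' @examples
#' m <- screenModel(c(W57 = 2, Q69 = 1, Q80 = 0, Q94 = 1, Q157 = 1,
#'                    Q177 = 1, Q183 = 1, Q184 = 1, Q204 = 0))
#' saturationSummary(m)
#' @export
screenModel <- function(multiplicities, weights = NULL, lambda = NULL,
                        includeZeros = TRUE) {
  x <- as.integer(round(multiplicities))
  nm <- names(multiplicities)
  if (is.null(nm)) nm <- sprintf("class%d", seq_along(x))
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  if (is.null(lambda))
    lambda <- fitRate(x, includeZeros = includeZeros, weights = w)
  new("ScreenModel", classes = nm, multiplicities = x, weights = w,
      lambda = as.numeric(lambda), includeZeros = includeZeros)
}

#' @rdname recoveryRate
#' @export
setMethod("recoveryRate", "ScreenModel", function(x) x@lambda)
#' @rdname multiplicities
#' @export
setMethod("multiplicities", "ScreenModel",
  function(x) structure(x@multiplicities, names = x@classes))
#' @rdname classWeights
#' @export
setMethod("classWeights", "ScreenModel",
  function(x) structure(x@weights, names = x@classes))

setMethod("show", "ScreenModel", function(object) {
  cat(sprintf("ScreenModel: %d classes, lambda = %.4g (%s fit)\n",
      length(object@classes), object@lambda,
      if (object@includeZeros) "full" else "zero-truncated"))
})

#' Saturation summary of a fitted screen model
#'
#' Closed-form saturation diagnostics under the Poisson recovery model:
#' per-class miss probabilities `exp(-lambda * w_i)`, the expected number
#' of unseen classes (their sum), the probability that every class was
#' seen (product of the complements), alongside the observed number of
#' never-recovered classes for comparison.
#'
#' @param model a [ScreenModel-class].
#' @return a list of class `"saturationSummary"` with fields `n_classes`,
#'   `lambda`, `per_class_miss`, `expected_unseen`, `p_all_seen`,
#'   `observed_unseen`, `observed_unseen_classes`.
#' @export
saturationSummary <- function(model) {
  stopifnot(is(model, "ScreenModel"))
  miss <- probClassMissed(model@lambda, model@weights)
  names(miss) <- model@classes
  out <- list(
    n_classes = length(model@classes),
    lambda = model@lambda,
    per_class_miss = miss,
    expected_unseen = sum(miss),
    p_all_seen = prod(1 - miss),
    observed_unseen = sum(model@multiplicities == 0L),
    observed_unseen_classes = model@classes[model@multiplicities == 0L])
  class(out) <- "saturationSummary"
  out
}

#' @export
print.saturationSummary <- function(x, ...) {
  cat("Saturation summary (per-class Poisson recovery model)\n")
  cat(sprintf("  classes: %d, fitted lambda: %.4g\n", x$n_classes, x$lambda))
  cat(sprintf("  expected unseen classes: %.3g\n", x$expected_unseen))
  cat(sprintf("  observed unseen classes: %d%s\n", x$observed_unseen,
      if (x$observed_unseen)
        paste0(" (", paste(x$observed_unseen_classes, collapse = ", "), ")")
      else ""))
  cat(sprintf("  P(all classes seen): %.3g\n", x$p_all_seen))
  invisible(x)
}

#' Read a class-multiplicity table
#'
#' TSV with columns `class_id`, `count` and optional `weight`.
#'
#' @param path TSV path.
#' @return a [ScreenModel-class] fitted with [screenModel()] defaults.
#' @export
readMultiplicities <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("class_id", "count") %in% names(d)))
    stop("multiplicity table needs columns 'class_id' and 'count'")
  screenModel(structure(as.integer(d$count), names = d$class_id),
              weights = if ("weight" %in% names(d)) d$weight else NULL)
}
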