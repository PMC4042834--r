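# Null calibration of the coherence statistic: size-stratified random gene
# sets, Nadaraya-Watson smoothing of their mean/variance, Gaussian p-values.

#' Default null size grid
#'
#' Sizes 5 to 50 in steps of 5, then 60 to 200 in steps of 20, spanning the
#' 5-200 gene range with finer resolution where small-set statistics change
#' fastest.
#'
#' @return integer vector of set sizes.
#' @export
defaultNullSizes <- function() {
  as.integer(c(seq(5L, 50L, 5L), seq(60L, 200L, 20L)))
}

#' Draw random gene sets and compute their coherence statistics
#'
#' For each size in the grid, draws `reps` gene sets uniformly without
#' replacement from the annotated gene universe (genes with at least one
#' direct annotation in the pruned graph) and computes the coherence
#' statistic of each. Fully reproducible from the seed.
#'
#' @param graph a [WeightedOntology-class] or [AugmentedOntology-class].
#' @param sizes integer vector of set sizes (default [defaultNullSizes()]).
#' @param reps replicates per size (default 100).
#' @param scheme `"plain"` or `"augmented"`.
#' @param seed integer random seed (required).
#' @return data.frame with columns `n` (set size) and `y` (statistic).
#' @export
sampleNull <- function(graph, sizes = defaultNullSizes(), reps = 100L,
                       scheme = c("plain", "augmented"), seed) {
  scheme <- match.arg(scheme)
  stopifnot(methods::is(graph, "WeightedOntology"))
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is required for reproducible sampling")
  universe <- geneUniverse(graph@ontology)
  sizes <- sort(unique(as.integer(sizes)))
  if (max(sizes) > length(universe))
    stop("requested set size ", max(sizes), " exceeds the annotated gene ",
         "universe (", length(universe), " genes)")
  set.seed(as.integer(seed))
  records <- vector("list", length(sizes) * reps)
  k <- 0L
  for (n in sizes) {
    for (r in seq_len(reps)) {
      g <- sample(universe, n)
      y <- geneSetStatistic(g, graph, scheme = scheme)@value
      k <- k + 1L
      records[[k]] <- c(n, y)
    }
  }
  m <- do.call(rbind, records)
  data.frame(n = as.integer(m[, 1]), y = m[, 2])
}

#' Fit the null model of the coherence statistic
#'
#' Wraps [sampleNull()] and stores the sampled statistics together with the
#' Nadaraya-Watson bandwidth used by [nwEstimate()] and [pValue()].
#'
#' @inheritParams sampleNull
#' @param h kernel bandwidth (default 10).
#' @return a [NullModel-class].
#' @export
fitNullModel <- function(graph, sizes = defaultNullSizes(), reps = 100L,
                         scheme = c("plain", "augmented"), seed, h = 10) {
  scheme <- match.arg(scheme)
  samples <- sampleNull(graph, sizes = sizes, reps = reps, scheme = scheme,
                        seed = seed)
  methods::new("NullModel", samples = samples, metric = graph@metric,
               scheme = scheme, h = h, seed = as.integer(seed),
               sizes = sort(unique(as.integer(sizes))),
               reps = as.integer(reps))
}

.nwCore <- function(ni, yi, n, h) {
  w <- exp(-(1 / h) * (ni - n)^2)
  sw <- sum(w)
  if (sw == 0 || !is.finite(sw))
    stop("all kernel weights are numerically zero at n = ", n,
         "; increase the bandwidth h")
  mu <- sum(w * yi) / sw
  s2 <- sum(w * (yi - mu)^2) / sw
  c(mean = mu, variance = s2)
}

#' Nadaraya-Watson estimate of the null mean and variance at a set size
#'
#' Kernel-weighted mean and variance of the sampled statistics,
#' mu(n) = sum w_n(n_i) y_i / sum w_n(n_i) and
#' sigma^2(n) = sum w_n(n_i) (y_i - mu(n))^2 / sum w_n(n_i), with the
#' Gaussian kernel w_n(n_i) = exp(-(1/h)(n_i - n)^2).
#'
#' @param x a [NullModel-class] or a data.frame with columns `n`, `y`.
#' @param n query set size (scalar or vector).
#' @param h bandwidth; defaults to the model's stored bandwidth (10).
#' @return for scalar `n`, a named vector `c(mean, variance)`; for vector
#'   `n`, a data.frame with columns `n`, `mean`, `variance`.
#' @export
setMethod("nwEstimate", "NullModel", function(x, n, h = NULL) {
  if (is.null(h)) h <- x@h
  nwEstimate(x@samples, n, h = h)
})

#' @rdname nwEstimate
#' @export
setMethod("nwEstimate", "data.frame", function(x, n, h = NULL) {
  stopifnot(all(c("n", "y") %in% names(x)), nrow(x) > 0)
  if (is.null(h)) h <- 10
  stopifnot(h > 0)
  if (length(n) == 1L) return(.nwCore(x$n, x$y, n, h))
  res <- t(vapply(n, function(nn) .nwCore(x$n, x$y, nn, h), numeric(2)))
  data.frame(n = n, mean = res[, 1], variance = res[, 2])
})

#' Lower-tail Gaussian p-value of an observed coherence statistic
#'
#' The probability that a random gene set of the same size attains a
#' statistic at most `y`, under the Gaussian null N(mu(n), sigma^2(n)) with
#' kernel-smoothed parameters. A smaller statistic means less information
#' loss, hence a smaller p-value and a more coherent gene set. Query sizes
#' outside the trained grid are extrapolated with a warning.
#'
#' @param x a fitted [NullModel-class].
#' @param n gene-set size.
#' @param y observed coherence statistic.
#' @return probability in (0, 1).
#' @export
setMethod("pValue", "NullModel", function(x, n, y) {
  stopifnot(length(n) == 1L, length(y) == 1L)
  if (n < min(x@sizes) || n > max(x@sizes))
    warning("set size ", n, " lies outside the trained grid [",
            min(x@sizes), ", ", max(x@sizes), "]; extrapolating")
  est <- nwEstimate(x, n)
  if (est[["variance"]] <= 0)
    stop("estimated null variance is zero at n = ", n,
         "; p-value undefined")
  stats::pnorm((y - est[["mean"]]) / sqrt(est[["variance"]]))
})

#' Cache a fitted null model as plain text
#'
#' Writes the sample table as TSV and the parameters (metric, scheme,
#' bandwidth, seed, sizes, reps) as a JSON sidecar, so the expensive
#' sampling step is done once per graph/metric/scheme.
#'
#' @param model a [NullModel-class].
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @return the base path, invisibly.
#' @export
writeNullModel <- function(model, path) {
  stopifnot(methods::is(model, "NullModel"))
  utils::write.table(model@samples, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(metric = model@metric, scheme = model@scheme, h = model@h,
         seed = model@seed, sizes = model@sizes, reps = model@reps),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNullModel
#' @export
readNullModel <- function(path) {
  samples <- utils::read.delim(paste0(path, ".tsv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  methods::new("NullModel",
               samples = data.frame(n = as.integer(samples$n),
                                    y = as.numeric(samples$y)),
               metric = meta$metric, scheme = meta$scheme,
               h = as.numeric(meta$h),
               seed = as.integer(meta$seed),
               sizes = as.integer(meta$sizes), reps = as.integer(meta$reps))
}
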