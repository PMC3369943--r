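#' Entropy difference divergence
#'
#' Absolute difference, in bits, between the entropies of two probability
#' tables on a common grid. Because the statistic is a difference of two
#' plug-in entropies, any additive estimation bias that is shared by both
#' terms cancels; no explicit bias correction is applied.
#'
#' @param p_data,p_ref Probability tables ([bivariate_pmf()] or matrices);
#'   zero padding to a common grid does not change either entropy, so tables
#'   of unequal dimensions are accepted as-is.
#' @return Nonnegative divergence in bits; 0 iff the entropies coincide.
#' @export
entropy_difference <- function(p_data, p_ref) {
  abs(entropy(p_data) - entropy(p_ref))
}

#' Mutual information between a stimulus and a count-pair response
#'
#' Plug-in mutual information \eqn{I(S; (X,Y))} for a discrete stimulus
#' ensemble with conditional response tables:
#' \deqn{I = \sum_s \pi(s) \sum_{x,y} P(x,y\mid s)
#'   \log_2 \frac{P(x,y\mid s)}{\sum_{s'} \pi(s') P(x,y\mid s')}.}
#'
#' @param conditionals List of probability tables, one per stimulus, padded
#'   to a common grid if their dimensions differ.
#' @param prior Stimulus probabilities; flat by default.
#' @return Mutual information in bits, in `[0, log2(length(conditionals))]`
#'   for a flat prior.
#' @export
mutual_information <- function(conditionals,
                               prior = rep(1, length(conditionals)) /
                                 length(conditionals)) {
  S <- length(conditionals)
  stopifnot(S >= 1, length(prior) == S)
  if (abs(sum(prior) - 1) > 1e-9)
    stop("invalid parameter: `prior` must sum to 1")
  nx <- max(vapply(conditionals, nrow, 1L))
  ny <- max(vapply(conditionals, ncol, 1L))
  conds <- lapply(conditionals, function(p) unclass(pad_pmf(p, nx, ny)))
  mix <- Reduce(`+`, Map(`*`, conds, prior))
  mi <- 0
  for (s in seq_len(S)) {
    pos <- conds[[s]] > 0
    mi <- mi + prior[s] *
      sum(conds[[s]][pos] * log2(conds[[s]][pos] / mix[pos]))
  }
  max(0, mi)
}

#' Stimulus ensemble of reference distributions
#'
#' Bundles one reference table per stimulus with a stimulus prior (flat by
#' default), for use with the mutual-information divergence.
#'
#' @param conditionals Named list of [bivariate_pmf()] tables, one per
#'   stimulus label.
#' @param prior Optional stimulus probabilities (flat if omitted).
#' @return An object of class `"stimulus_ensemble"`.
#' @export
stimulus_ensemble <- function(conditionals, prior = NULL) {
  if (is.null(names(conditionals)) || anyDuplicated(names(conditionals)))
    stop("labeling error: `conditionals` must have unique stimulus names")
  if (is.null(prior)) prior <- rep(1, length(conditionals)) /
      length(conditionals)
  if (abs(sum(prior) - 1) > 1e-9)
    stop("invalid parameter: `prior` must sum to 1")
  structure(list(stimuli = names(conditionals), prior = prior,
                 conditionals = conditionals),
            class = "stimulus_ensemble")
}

#' Mutual information difference divergence
#'
#' Absolute difference, in bits, between the plug-in mutual information of
#' the per-stimulus empirical distributions of a labelled sample and the
#' mutual information of the reference ensemble, both under the ensemble's
#' stimulus prior.
#'
#' @param data A labelled [count_pairs()] sample.
#' @param refs A [stimulus_ensemble()]; every stimulus label occurring in
#'   `data` must be present.
#' @return Nonnegative divergence in bits.
#' @export
mi_difference <- function(data, refs) {
  if (is.null(data$stimulus))
    stop("labeling error: the mutual-information divergence needs a labelled sample")
  labs <- unique(data$stimulus)
  if (!all(labs %in% refs$stimuli))
    stop("labeling error: sample contains stimuli absent from the reference ensemble")
  nx <- max(vapply(refs$conditionals, nrow, 1L), data$x + 1L)
  ny <- max(vapply(refs$conditionals, ncol, 1L), data$y + 1L)
  sup <- support_from_dims(nx, ny)
  emp <- lapply(refs$stimuli, function(s) {
    d <- data[data$stimulus == s, , drop = FALSE]
    if (nrow(d) < 1L)
      stop("labeling error: no observations for stimulus ", s)
    pad_pmf(empirical_pmf(count_pairs(d$x, d$y), sup), nx, ny)
  })
  refc <- lapply(refs$conditionals, pad_pmf, nx = nx, ny = ny)
  abs(mutual_information(emp, refs$prior) -
        mutual_information(refc, refs$prior))
}

#' Divergence measure handles
#'
#' The Monte Carlo test is parameterized by a divergence measure comparing an
#' empirical distribution with the maximum entropy reference. Two measures
#' ship with the package (`"entropy_diff"`, `"mi_diff"`); arbitrary
#' user-defined statistics can be supplied as a function
#' `function(empirical_tables, reference_tables, prior)` returning a single
#' nonnegative number, where the tables are lists with one entry per stimulus
#' (a single unlabelled sample is treated as one stimulus).
#'
#' @param name `"entropy_diff"`, `"mi_diff"`, or a function as described.
#' @return An object of class `"divergence_measure"`.
#' @export
divergence_measure <- function(name = c("entropy_diff", "mi_diff")) {
  if (is.function(name))
    return(structure(list(name = "custom", fun = name),
                     class = "divergence_measure"))
  name <- match.arg(name)
  fun <- switch(name,
    entropy_diff = function(emp, ref, prior) {
      abs(entropy(emp[[1]]) - entropy(ref[[1]]))
    },
    mi_diff = function(emp, ref, prior) {
      abs(mutual_information(emp, prior) - mutual_information(ref, prior))
    })
  structure(list(name = name, fun = fun), class = "divergence_measure")
}

as_divergence <- function(x) {
  if (inherits(x, "divergence_measure")) return(x)
  divergence_measure(x)
}
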