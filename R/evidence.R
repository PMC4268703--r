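#' An item of identification evidence
#'
#' One line of evidence about whether remains belong to the target
#' individual, carrying either a pair of likelihoods under the two competing
#' hypotheses -- H1: the remains are the target; H2: they are not -- or a
#' pre-computed likelihood ratio.  Items are assumed mutually independent and
#' combine multiplicatively (see [combine_evidence()]).
#'
#' @param name short unique item name.
#' @param lik_h1,lik_h2 likelihoods of the observed data under H1 / H2
#'   (`likelihood_pair` form); `lik_h2` must be positive, `lik_h1`
#'   non-negative.
#' @param lr pre-computed positive likelihood ratio (`fixed_lr` form);
#'   mutually exclusive with the likelihood pair.
#' @param category `"genetic"` or `"non_genetic"`, used when forming the
#'   canonical evidence subsets.
#' @param conservative optional annotation recording the direction in which
#'   the item's assumptions bias its LR: `"down"` (assumptions reduce the
#'   LR, the usual conservative convention), `"up"`, or `"neutral"`.
#'   Documentation metadata only; never used in computation.
#' @param notes free-text provenance.
#' @return object of class `evidence_item`.
#' @export
evidence_item <- function(name, lik_h1 = NULL, lik_h2 = NULL, lr = NULL,
                          category = c("non_genetic", "genetic"),
                          conservative = NA_character_, notes = "") {
  stopifnot(is_string(name))
  category <- match.arg(category)
  has_pair <- !is.null(lik_h1) || !is.null(lik_h2)
  if (has_pair && !is.null(lr))
    kinlr_stop("kinlr_bad_argument",
               "give either a likelihood pair or a fixed lr, not both")
  if (has_pair) {
    if (!is_prob(lik_h1) || !is_prob(lik_h2, open_left = TRUE))
      kinlr_stop("kinlr_bad_argument",
                 "need 0 <= lik_h1 <= 1 and 0 < lik_h2 <= 1")
    form <- "likelihood_pair"
  } else {
    if (!is.numeric(lr) || length(lr) != 1L || !is.finite(lr) || lr <= 0)
      kinlr_stop("kinlr_bad_argument", "fixed lr must be a positive number")
    form <- "fixed_lr"
  }
  structure(list(name = name, form = form,
                 lik_h1 = lik_h1, lik_h2 = lik_h2, lr = lr,
                 category = category,
                 conservative = as.character(conservative),
                 notes = as.character(notes)),
            class = "evidence_item")
}

#' Likelihood ratio of a single evidence item
#'
#' @param item an [evidence_item()].
#' @return `lik_h1 / lik_h2` for a likelihood pair, or the stored fixed LR.
#' @export
ev_lr <- function(item) {
  stopifnot(inherits(item, "evidence_item"))
  if (item$form == "fixed_lr") item$lr else item$lik_h1 / item$lik_h2
}

#' @export
print.evidence_item <- function(x, ...) {
  cat(sprintf("<evidence_item> %s [%s, %s]: LR = %s\n", x$name, x$category,
              x$form, format(ev_lr(x), digits = 4)))
  invisible(x)
}

#' Prior probability of identity
#'
#' @param p probability, strictly between 0 and 1, that the remains are the
#'   target individual before any of the itemised evidence is considered.
#' @return object of class `kinlr_prior`.
#' @export
prior <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    kinlr_stop("kinlr_bad_argument", "prior must lie strictly in (0, 1)")
  structure(list(p = p), class = "kinlr_prior")
}

as_prior_p <- function(x) if (inherits(x, "kinlr_prior")) x$p else prior(x)$p

#' Posterior probability of identity
#'
#' Bayes' rule in odds form: posterior odds = LR x prior odds, i.e.
#' `posterior = lr * p / (lr * p + (1 - p))`.  Computed in a form stable for
#' very large LRs.  `not_h1_probability()` returns the complement
#' `(1 - p) / (lr * p + (1 - p))`, the probability that the remains are NOT
#' the target, computed directly to retain precision when the posterior is
#' close to 1.
#'
#' @param prior_p prior probability of H1 (a number in (0,1) or a
#'   [prior()]).
#' @param lr combined likelihood ratio (non-negative).
#' @return probability.
#' @export
posterior_prob <- function(prior_p, lr) {
  p <- as_prior_p(prior_p)
  if (!is.numeric(lr) || length(lr) != 1L || is.na(lr) || lr < 0)
    kinlr_stop("kinlr_bad_argument", "lr must be a non-negative number")
  if (is.infinite(lr)) return(1)
  lr * p / (lr * p + (1 - p))
}

#' @rdname posterior_prob
#' @export
not_h1_probability <- function(prior_p, lr) {
  p <- as_prior_p(prior_p)
  if (!is.numeric(lr) || length(lr) != 1L || is.na(lr) || lr < 0)
    kinlr_stop("kinlr_bad_argument", "lr must be a non-negative number")
  if (is.infinite(lr)) return(0)
  (1 - p) / (lr * p + (1 - p))
}

#' Combine independent evidence items into an overall likelihood ratio
#'
#' Under the independence assumption the joint likelihood of all the
#' evidence under each hypothesis is the product of the item likelihoods, so
#' the overall LR is the product of the item LRs.  The product is accumulated
#' in log space to avoid under/overflow; items with LR 1 are no-ops and the
#' result is invariant to item order.  An empty item list yields the neutral
#' LR 1 (the prior is returned unchanged).
#'
#' @param items list of [evidence_item()] (possibly empty).
#' @param priors numeric vector of prior probabilities (or list of
#'   [prior()]), each converted to a posterior in the result.
#' @return object of class `lr_analysis`: list with `items`, per-item `lrs`,
#'   `log_lr`, `lr`, and a data frame `posteriors` (prior, posterior,
#'   p_not_h1).
#' @examples
#' items <- list(evidence_item("radiocarbon", lr = 1.84),
#'               evidence_item("wounds", lr = 42))
#' fit <- combine_evidence(items, priors = c(0.025, 0.5))
#' fit$lr
#' @export
combine_evidence <- function(items, priors = numeric(0)) {
  stopifnot(is.list(items))
  for (it in items)
    if (!inherits(it, "evidence_item"))
      kinlr_stop("kinlr_bad_argument", "items must all be evidence_item objects")
  lrs <- vapply(items, ev_lr, numeric(1))
  names(lrs) <- vapply(items, `[[`, "", "name")
  log_lr <- sum(log(lrs))   # sum(empty) = 0 -> neutral LR 1
  lr <- exp(log_lr)
  ps <- vapply(priors, as_prior_p, numeric(1))
  posteriors <- data.frame(
    prior = ps,
    posterior = vapply(ps, function(p) posterior_prob(p, lr), numeric(1)),
    p_not_h1 = vapply(ps, function(p) not_h1_probability(p, lr), numeric(1)))
  structure(list(items = items, lrs = lrs, log_lr = log_lr, lr = lr,
                 posteriors = posteriors),
            class = "lr_analysis")
}

#' @export
print.lr_analysis <- function(x, ...) {
  cat(sprintf("<lr_analysis> %d evidence item(s), combined LR = %s\n",
              length(x$items), format_lr(x$lr)))
  if (nrow(x$posteriors) > 0L) {
    for (i in seq_len(nrow(x$posteriors)))
      cat(sprintf("  prior %-7s -> posterior %s\n",
                  format(x$posteriors$prior[i]),
                  format_posterior(x$posteriors$posterior[i])))
  }
  invisible(x)
}

#' @export
summary.lr_analysis <- function(object, ...) {
  cat(sprintf("Combined likelihood ratio: %s (log LR = %.4f)\n",
              format_lr(object$lr), object$log_lr))
  if (length(object$lrs) > 0L) {
    cat("Per-item likelihood ratios:\n")
    for (nm in names(object$lrs))
      cat(sprintf("  %-14s %s\n", nm, format_lr(object$lrs[[nm]])))
  }
  if (nrow(object$posteriors) > 0L) {
    cat("Posterior probabilities:\n")
    print(object$posteriors, row.names = FALSE)
  }
  invisible(object)
}

# Reporting precision convention: LRs >= 100 to 3 significant figures,
# smaller LRs to 3 significant figures as-is; posteriors with enough digits
# to distinguish them from 1.
format_lr <- function(lr) {
  if (!is.finite(lr)) return(as.character(lr))
  if (lr >= 1e6) sprintf("%.2f million", lr / 1e6)
  else format(signif(lr, 3), big.mark = ",", scientific = FALSE)
}

format_posterior <- function(p) {
  if (p >= 1 - 1e-12) return("~1")
  digits <- max(4L, ceiling(-log10(1 - p)) + 1L)
  formatC(p, digits = digits, format = "f")
}

#' Scoliosis evidence likelihood ratio
#'
#' The historical description of the target ("one shoulder higher than the
#' other") could be explained by scoliosis or by two much rarer conditions
#' (Erb's palsy, Sprengel's deformity).  Under H1 the probability of
#' observing scoliosis in the remains given the description is the scoliosis
#' rate divided by the sum of the three condition rates, discounted by the
#' probability `p_record` that the recorded description is correct.  Under
#' H2 the probability of the skeletal finding is the population probability
#' `p_pop`.  LR = (share x p_record) / p_pop.
#'
#' @param rate_s,rate_e,rate_sp population rates of scoliosis, Erb's palsy
#'   and Sprengel's deformity (any common proportional unit).
#' @param p_record probability the historical description is correct.
#' @param p_pop probability of observing the skeletal finding under H2.
#' @return likelihood ratio.
#' @export
scoliosis_lr <- function(rate_s, rate_e, rate_sp, p_record, p_pop) {
  rates <- c(rate_s, rate_e, rate_sp)
  if (!all(vapply(rates, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0, logical(1))) ||
      sum(rates) <= 0)
    kinlr_stop("kinlr_bad_argument", "condition rates must be >= 0 with positive sum")
  if (!is_prob(p_record, open_left = TRUE) || !is_prob(p_pop, open_left = TRUE))
    kinlr_stop("kinlr_bad_argument", "p_record and p_pop must lie in (0, 1]")
  share <- rate_s / sum(rates)
  share * p_record / p_pop
}

#' Likelihood ratios and posteriors over evidence subsets
#'
#' Builds the combination table: one row per named subset of the evidence,
#' with the combined LR and the posterior probability under each prior.
#' The empty subset is defined as the neutral LR 1 (prior unchanged).
#'
#' @param items named list of [evidence_item()] (names taken from the items).
#' @param subsets named list of character vectors of item names; defaults to
#'   [canonical_subsets()] of the items.
#' @param priors numeric vector of prior probabilities.
#' @return data frame with columns `subset`, `n_items`, `lr`, and one
#'   posterior column per prior.
#' @export
lr_table <- function(items, subsets = NULL, priors = c(0.025, 0.5)) {
  names(items) <- vapply(items, `[[`, "", "name")
  if (is.null(subsets)) subsets <- canonical_subsets(items)
  ps <- vapply(priors, as_prior_p, numeric(1))
  rows <- lapply(names(subsets), function(sn) {
    sel <- subsets[[sn]]
    unknown <- setdiff(sel, names(items))
    if (length(unknown) > 0L)
      kinlr_stop("kinlr_unknown_item", "unknown evidence item(s) in subset %s: %s",
                 sn, paste(unknown, collapse = ", "))
    fit <- combine_evidence(items[sel], priors = ps)
    row <- data.frame(subset = sn, n_items = length(sel), lr = fit$lr)
    for (i in seq_along(ps))
      row[[sprintf("posterior_p%s", format(ps[i]))]] <- fit$posteriors$posterior[i]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Canonical evidence subsets
#'
#' The four standard subsets reported for a combined genetic + non-genetic
#' identification: all items; non-genetic only; genetic only; and genetic
#' without the Y-chromosome item (whose susceptibility to false paternity
#' makes it the weakest genetic component).
#'
#' @param items named list of [evidence_item()].
#' @param y_item name of the Y-chromosome item (default any item whose name
#'   contains `"y_"` or equals `"y_chromosome"`).
#' @return named list of character vectors.
#' @export
canonical_subsets <- function(items, y_item = NULL) {
  nms <- vapply(items, `[[`, "", "name")
  names(items) <- nms
  genetic <- nms[vapply(items, `[[`, "", "category") == "genetic"]
  if (is.null(y_item))
    y_item <- genetic[grepl("^y($|_)|y_chromosome", genetic)]
  list(all = nms,
       non_genetic = setdiff(nms, genetic),
       genetic = genetic,
       genetic_no_y = setdiff(genetic, y_item))
}
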