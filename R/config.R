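# Evidence configuration JSON: a versioned list of evidence items plus the
# priors under which posteriors are reported.
#
# {
#   "version": 1,
#   "items": [
#     {"name": "radiocarbon", "form": "fixed_lr", "lr": 1.84,
#      "category": "non_genetic", "conservative": "down", "notes": "..."},
#     {"name": "mtdna", "form": "likelihood_pair",
#      "lik_h1": 0.52, "lik_h2": 0.0010917, "category": "genetic"}
#   ],
#   "priors": [0.025, 0.5]
# }

#' Read / write an evidence configuration (JSON)
#'
#' @param path JSON file path.
#' @return `read_evidence_config()` returns a list with `items` (list of
#'   [evidence_item()]) and `priors` (numeric vector).
#' @export
read_evidence_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$version) || cfg$version != 1L)
    kinlr_stop("kinlr_bad_config", "unsupported or missing config version")
  if (is.null(cfg$items))
    kinlr_stop("kinlr_bad_config", "config lacks an 'items' list")
  items <- lapply(cfg$items, function(it) {
    if (is.null(it$name) || is.null(it$form))
      kinlr_stop("kinlr_bad_config", "every item needs 'name' and 'form'")
    if (it$form == "fixed_lr") {
      evidence_item(it$name, lr = it$lr,
                    category = it$category %||% "non_genetic",
                    conservative = it$conservative %||% NA_character_,
                    notes = it$notes %||% "")
    } else if (it$form == "likelihood_pair") {
      evidence_item(it$name, lik_h1 = it$lik_h1, lik_h2 = it$lik_h2,
                    category = it$category %||% "non_genetic",
                    conservative = it$conservative %||% NA_character_,
                    notes = it$notes %||% "")
    } else {
      kinlr_stop("kinlr_bad_config", "unknown item form: %s", it$form)
    }
  })
  names(items) <- vapply(items, `[[`, "", "name")
  priors <- as.numeric(unlist(cfg$priors))
  for (p in priors) prior(p)  # validate
  list(items = items, priors = priors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_evidence_config
#' @param items list of [evidence_item()].
#' @param priors numeric vector of prior probabilities.
#' @export
write_evidence_config <- function(items, priors, path) {
  out <- list(
    version = 1L,
    items = lapply(items, function(it) {
      base <- list(name = it$name, form = it$form, category = it$category)
      if (it$form == "fixed_lr") base$lr <- it$lr
      else { base$lik_h1 <- it$lik_h1; base$lik_h2 <- it$lik_h2 }
      if (!is.na(it$conservative)) base$conservative <- it$conservative
      if (nzchar(it$notes)) base$notes <- it$notes
      base
    }),
    priors = as.numeric(priors))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
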