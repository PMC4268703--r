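#' Declared rCRS position ranges
#'
#' Haplotypes are expressed as differences from the revised Cambridge
#' Reference Sequence (rCRS) over explicitly declared position ranges -- for
#' the forensic control-region comparisons here, typically
#' `"16093-16320 73-188"`.  Ranges are 1-based and inclusive; there is no
#' wrap-around range object (the control region spanning the origin is simply
#' written as two ranges).
#'
#' @param spec either a string like `"16093-16320 73-188"` or a two-column
#'   numeric matrix/data frame of (start, end) pairs.
#' @param max_pos largest legal position (rCRS length 16,569 by default;
#'   smaller for toy references).
#' @return object of class `mt_ranges`: data frame with columns `start`,
#'   `end`.
#' @export
mt_ranges <- function(spec, max_pos = 16569L) {
  if (inherits(spec, "mt_ranges")) return(spec)
  if (is.character(spec)) {
    stopifnot(length(spec) == 1L)
    tokens <- strsplit(trimws(spec), "[[:space:],]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L)
      kinlr_stop("kinlr_bad_range", "empty range specification")
    parts <- regmatches(tokens, regexec("^([0-9]+)-([0-9]+)$", tokens))
    if (any(lengths(parts) != 3L))
      kinlr_stop("kinlr_bad_range", "malformed range token(s): %s",
                 paste(tokens[lengths(parts) != 3L], collapse = ", "))
    df <- data.frame(start = as.integer(vapply(parts, `[`, "", 2L)),
                     end = as.integer(vapply(parts, `[`, "", 3L)))
  } else {
    df <- as.data.frame(spec)
    names(df) <- c("start", "end")
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  }
  if (any(df$start < 1L) || any(df$end > max_pos) || any(df$start > df$end))
    kinlr_stop("kinlr_bad_range",
               "ranges must satisfy 1 <= start <= end <= %d", max_pos)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mt_ranges", "data.frame")
  df
}

format_ranges <- function(r) paste(sprintf("%d-%d", r$start, r$end), collapse = " ")

in_ranges <- function(pos, r) {
  vapply(pos, function(p) any(p >= r$start & p <= r$end), logical(1))
}

ranges_intersect <- function(r1, r2) {
  out <- list()
  for (i in seq_len(nrow(r1))) for (j in seq_len(nrow(r2))) {
    s <- max(r1$start[i], r2$start[j]); e <- min(r1$end[i], r2$end[j])
    if (s <= e) out[[length(out) + 1L]] <- c(s, e)
  }
  if (length(out) == 0L) return(NULL)
  mt_ranges(do.call(rbind, out))
}

# TRUE if every position of `inner` is covered by `outer`.
ranges_covered_by <- function(inner, outer) {
  for (i in seq_len(nrow(inner))) {
    pos <- inner$start[i]
    repeat {
      j <- which(outer$start <= pos & outer$end >= pos)
      if (length(j) == 0L) return(FALSE)
      pos <- max(outer$end[j]) + 1L
      if (pos > inner$end[i]) break
    }
  }
  TRUE
}

# Variant token grammar: substitutions "16126C"; insertions "315.1C";
# deletions "249DEL".  Anything else (including heteroplasmy/ambiguity codes
# other than N) is rejected rather than silently interpreted.
TOKEN_SUB <- "^([0-9]+)([ACGT])$"
TOKEN_INDEL <- "^([0-9]+)(\\.[0-9]+[ACGT]|DEL)$"

token_position <- function(tok) {
  as.integer(sub("^([0-9]+).*$", "\\1", tok))
}

#' mtDNA haplotype as named differences from a reference
#'
#' @param variants character vector of variant tokens: substitutions
#'   (`"16126C"`), insertions (`"315.1C"`) or deletions (`"249DEL"`).
#'   Insertion/deletion tokens are treated as opaque strings compared by
#'   equality; no indel realignment is attempted.  Tokens are stored
#'   uppercase.
#' @param ranges declared covered positions (see [mt_ranges()]).
#' @param max_pos largest legal position (passed to [mt_ranges()]).
#' @return object of class `mt_haplotype` with fields `variants` (sorted by
#'   position) and `ranges`.
#' @export
mt_haplotype <- function(variants = character(0), ranges, max_pos = 16569L) {
  ranges <- mt_ranges(ranges, max_pos = max_pos)
  variants <- toupper(trimws(as.character(variants)))
  variants <- variants[nzchar(variants)]
  is_sub <- grepl(TOKEN_SUB, variants)
  is_indel <- grepl(TOKEN_INDEL, variants)
  bad <- variants[!is_sub & !is_indel]
  if (length(bad) > 0L)
    kinlr_stop("kinlr_bad_token", "malformed variant token(s): %s",
               paste(bad, collapse = ", "))
  sub_pos <- token_position(variants[is_sub])
  if (anyDuplicated(sub_pos))
    kinlr_stop("kinlr_duplicate_position",
               "multiple substitutions at position(s): %s",
               paste(unique(sub_pos[duplicated(sub_pos)]), collapse = ", "))
  out_of_range <- sub_pos[!in_ranges(sub_pos, ranges)]
  if (length(out_of_range) > 0L)
    kinlr_stop("kinlr_out_of_range",
               "substitution(s) outside declared ranges: %s",
               paste(out_of_range, collapse = ", "))
  variants <- variants[order(token_position(variants), variants)]
  structure(list(variants = variants, ranges = ranges),
            class = "mt_haplotype")
}

#' @export
print.mt_haplotype <- function(x, ...) {
  cat(sprintf("<mt_haplotype> %d variant(s) over ranges %s\n",
              length(x$variants), format_ranges(x$ranges)))
  if (length(x$variants) > 0L)
    cat(" ", paste(x$variants, collapse = " "), "\n")
  invisible(x)
}

#' Parse an EMPOP-style variant profile string
#'
#' @param text whitespace-separated variant tokens; the empty string denotes
#'   an rCRS-identical haplotype over the declared ranges.
#' @inheritParams mt_haplotype
#' @return an [mt_haplotype()].
#' @export
parse_variant_profile <- function(text, ranges, max_pos = 16569L) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  mt_haplotype(tokens, ranges, max_pos = max_pos)
}

#' Derive a haplotype from an aligned sequence
#'
#' Compares an rCRS-aligned sequence against the reference position by
#' position over the declared ranges and emits a substitution token wherever
#' the two differ and neither base is `N`.  The sequences must already be
#' aligned (equal length, 1-based shared coordinates); no indel realignment
#' is performed, so this captures substitutions only.
#'
#' @param seq,reference equal-length DNA strings (or objects coercible via
#'   `as.character`, e.g. a `Biostrings::DNAString`).
#' @inheritParams mt_haplotype
#' @return an [mt_haplotype()] with `max_pos` equal to the sequence length.
#' @export
profile_from_fasta <- function(seq, reference, ranges) {
  seq <- toupper(as.character(seq)); reference <- toupper(as.character(reference))
  stopifnot(length(seq) == 1L, length(reference) == 1L)
  if (nchar(seq) != nchar(reference))
    kinlr_stop("kinlr_length_mismatch",
               "sequence length %d != reference length %d",
               nchar(seq), nchar(reference))
  s <- strsplit(seq, "")[[1]]; r <- strsplit(reference, "")[[1]]
  bad <- unique(c(s, r)[!(c(s, r) %in% c("A", "C", "G", "T", "N"))])
  if (length(bad) > 0L)
    kinlr_stop("kinlr_bad_base",
               "unsupported base character(s) (only A/C/G/T/N allowed): %s",
               paste(bad, collapse = ", "))
  ranges <- mt_ranges(ranges, max_pos = nchar(reference))
  pos <- which(s != r & s != "N" & r != "N")
  pos <- pos[in_ranges(pos, ranges)]
  mt_haplotype(sprintf("%d%s", pos, s[pos]), ranges,
               max_pos = nchar(reference))
}

#' Read aligned sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` returning a named
#' character vector, for feeding reference-aligned records to
#' [profile_from_fasta()].
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_mt_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    kinlr_stop("kinlr_missing_dependency",
               "reading FASTA requires the Biostrings package")
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Differences between two haplotypes over their shared ranges
#'
#' Comparison is restricted to the intersection of the two declared range
#' sets; tokens (substitutions by position, indels as opaque strings) present
#' in exactly one haplotype within the shared ranges are returned sorted.  An
#' empty result means the haplotypes match over the comparable positions.
#'
#' @param h1,h2 [mt_haplotype()] objects.
#' @return sorted character vector of discordant tokens (empty = match).
#'   Raises a `kinlr_no_comparable_positions` condition if the declared
#'   ranges do not overlap.
#' @export
mt_diff <- function(h1, h2) {
  stopifnot(inherits(h1, "mt_haplotype"), inherits(h2, "mt_haplotype"))
  shared <- ranges_intersect(h1$ranges, h2$ranges)
  if (is.null(shared))
    kinlr_stop("kinlr_no_comparable_positions",
               "declared ranges do not overlap; no comparable positions")
  restrict <- function(h) h$variants[in_ranges(token_position(h$variants), shared)]
  v1 <- restrict(h1); v2 <- restrict(h2)
  d <- union(setdiff(v1, v2), setdiff(v2, v1))
  d[order(token_position(d), d)]
}

#' mtDNA haplotype database
#'
#' @param ids character vector of record ids (unique).
#' @param haplotypes list of [mt_haplotype()] of the same length.
#' @return object of class `mt_db`.
#' @export
mt_db <- function(ids = character(0), haplotypes = list()) {
  ids <- as.character(ids)
  stopifnot(length(ids) == length(haplotypes))
  if (anyDuplicated(ids))
    kinlr_stop("kinlr_duplicate_id", "duplicate database record id(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (h in haplotypes) stopifnot(inherits(h, "mt_haplotype"))
  structure(list(ids = ids, haplotypes = haplotypes), class = "mt_db")
}

#' @export
length.mt_db <- function(x) length(x$ids)

#' @export
print.mt_db <- function(x, ...) {
  cat(sprintf("<mt_db> %d haplotype record(s)\n", length(x)))
  invisible(x)
}

#' Read / write a haplotype database TSV
#'
#' Columns `id`, `ranges` (e.g. `"16093-16320 73-188"`), `variants`
#' (space-separated tokens; empty = rCRS-identical).
#'
#' @param path file path.
#' @param max_pos largest legal position.
#' @return `read_mt_db()` returns an [mt_db()]; the writer returns `path`
#'   invisibly.
#' @export
read_mt_db <- function(path, max_pos = 16569L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", na.strings = NULL)
  haps <- lapply(seq_len(nrow(df)), function(i)
    parse_variant_profile(df$variants[i], df$ranges[i], max_pos = max_pos))
  mt_db(df$id, haps)
}

#' @rdname read_mt_db
#' @param db an [mt_db()].
#' @export
write_mt_db <- function(db, path) {
  stopifnot(inherits(db, "mt_db"))
  df <- data.frame(
    id = db$ids,
    ranges = vapply(db$haplotypes, function(h) format_ranges(h$ranges), ""),
    variants = vapply(db$haplotypes, function(h)
      paste(h$variants, collapse = " "), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Count database records matching a query haplotype
#'
#' A record matches if its restriction to the comparison ranges is identical
#' to the query's restriction.  Records whose declared ranges do not fully
#' cover the comparison ranges are skipped (not counted as matches or
#' mismatches) and reported via the `skipped` attribute.
#'
#' @param db an [mt_db()].
#' @param query an [mt_haplotype()].
#' @param ranges comparison ranges; default: the query's declared ranges.
#' @return integer match count `k`, with attribute `skipped` (number of
#'   records not covering the comparison ranges).
#' @export
count_db_matches <- function(db, query, ranges = query$ranges) {
  stopifnot(inherits(db, "mt_db"), inherits(query, "mt_haplotype"))
  ranges <- mt_ranges(ranges, max_pos = .Machine$integer.max)
  restrict <- function(h) {
    v <- h$variants[in_ranges(token_position(h$variants), ranges)]
    paste(v, collapse = " ")
  }
  qkey <- restrict(query)
  k <- 0L; skipped <- 0L
  for (h in db$haplotypes) {
    if (!ranges_covered_by(ranges, h$ranges)) { skipped <- skipped + 1L; next }
    if (identical(restrict(h), qkey)) k <- k + 1L
  }
  structure(k, skipped = skipped)
}

#' Conservative haplotype match probability
#'
#' Estimates the probability that a random member of the reference population
#' carries the query haplotype, from `k` matches in a database of size `n`.
#' The default convention deliberately biases the resulting likelihood ratio
#' toward the neutral value 1: the sampled relative who shares the haplotype
#' is added to both numerator and denominator (`add_relative`), and a
#' pseudocount is added to the numerator so the estimate can never be zero.
#'
#' `match_probability(k, n) = (k + add_relative + pseudocount) / (n + add_relative)`
#'
#' With the defaults, a zero-match search of a database of 1,831 yields
#' 2/1,832.  Setting `add_relative = FALSE, pseudocount = 0` gives the plain
#' relative frequency `k/n`.
#'
#' @param k observed match count (`0 <= k <= n`).
#' @param n database size.
#' @param add_relative logical; add the known matching relative to both
#'   counts (default `TRUE`).
#' @param pseudocount non-negative count added to the numerator (default 1).
#' @return match probability in (0, 1].
#' @export
match_probability <- function(k, n, add_relative = TRUE, pseudocount = 1) {
  if (!is_count(k) || !is_count(n) || k > n)
    kinlr_stop("kinlr_bad_argument", "need integer 0 <= k <= n")
  if (!is_count(pseudocount))
    kinlr_stop("kinlr_bad_argument", "pseudocount must be a non-negative integer")
  rel <- as.integer(isTRUE(add_relative))
  num <- k + rel + pseudocount
  den <- n + rel
  if (num == 0)
    kinlr_warn("kinlr_zero_estimate",
               "match probability estimate is zero; the mtDNA LR will be infinite")
  num / den
}

#' Probability of no control-region mutation over m meioses
#'
#' With per-meiosis mutation probability `mu`, the probability that a
#' haplotype is transmitted unchanged down `m` meioses is `(1 - mu)^m`.
#' High `mu` estimates are conservative here (they lower the H1 likelihood
#' of the observed match); the pedigree-based rate of 10 control-region
#' mutations in 327 generations (`mu = 10/327`) is a standard conservative
#' choice.
#'
#' @param mu per-meiosis mutation probability, in `[0, 1)`.
#' @param m number of meioses (non-negative integer).
#' @return probability in (0, 1].
#' @export
no_mutation_prob <- function(mu, m) {
  if (!is_prob(mu, open_right = TRUE))
    kinlr_stop("kinlr_bad_argument", "mu must lie in [0, 1)")
  if (!is_count(m))
    kinlr_stop("kinlr_bad_argument", "m must be a non-negative integer")
  (1 - mu)^m
}

#' mtDNA evidence likelihood ratio
#'
#' For an observed mtDNA match between the remains and a matrilineal relative
#' separated by `m` meioses: the likelihood of the match under H1 (same
#' individual) is the no-mutation probability `(1 - mu)^m`; under H2
#' (unrelated individual) it is the population match probability of the
#' shared haplotype.  Their ratio is the evidence LR.  Either supply `mu`
#' and `m`, or supply a pre-computed `p_no_mutation` directly.
#'
#' @inheritParams no_mutation_prob
#' @param p_match population match probability of the shared haplotype
#'   (see [match_probability()]); must be positive.
#' @param p_no_mutation optional: numerator probability, overriding the
#'   `(1 - mu)^m` computation.
#' @return likelihood ratio (positive).
#' @export
mtdna_lr <- function(p_match, mu = NULL, m = NULL, p_no_mutation = NULL) {
  if (!is_prob(p_match, open_left = TRUE))
    kinlr_stop("kinlr_bad_argument", "p_match must lie in (0, 1]")
  if (is.null(p_no_mutation)) {
    if (is.null(mu) || is.null(m))
      kinlr_stop("kinlr_bad_argument",
                 "supply either p_no_mutation or both mu and m")
    p_no_mutation <- no_mutation_prob(mu, m)
  } else if (!is_prob(p_no_mutation)) {
    kinlr_stop("kinlr_bad_argument", "p_no_mutation must lie in [0, 1]")
  }
  p_no_mutation / p_match
}

#' Likelihood ratio contribution of a second matching relative
#'
#' When a second matrilineal relative's haplotype is observed in addition to
#' the first's, its probability is assessed conditionally on the first
#' relative's sequence.  That conditional probability is the same whether or
#' not the remains belong to the target (H1 vs H2), so the observation
#' cancels in the likelihood ratio: the contribution is exactly 1.  This
#' holds regardless of whether the second relative matched perfectly or (as
#' with a single-site difference accrued on its own branch) nearly.
#'
#' @return exactly 1.
#' @export
second_relative_lr <- function() 1
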