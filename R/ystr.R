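#' Y-STR locus panel
#'
#' @param loci character vector of unique locus names, in reporting order.
#' @param multi_copy subset of `loci` whose value is a multiset of alleles
#'   (multi-copy loci such as DYS385a/b, reported as one comma-separated
#'   cell).
#' @return object of class `ystr_panel`.
#' @export
ystr_panel <- function(loci, multi_copy = character(0)) {
  loci <- as.character(loci)
  if (anyDuplicated(loci))
    kinlr_stop("kinlr_duplicate_id", "duplicate locus name(s): %s",
               paste(unique(loci[duplicated(loci)]), collapse = ", "))
  if (!all(multi_copy %in% loci))
    kinlr_stop("kinlr_bad_argument",
               "multi_copy loci not in panel: %s",
               paste(setdiff(multi_copy, loci), collapse = ", "))
  structure(list(loci = loci, multi_copy = as.character(multi_copy)),
            class = "ystr_panel")
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat(sprintf("<ystr_panel> %d loci (%d multi-copy)\n",
              length(x$loci), length(x$multi_copy)))
  invisible(x)
}

#' The 23-locus PowerPlex Y23 panel
#'
#' Default panel: the 23 loci of the Promega PowerPlex Y23 system, with
#' DYS385 (a/b) as the single multi-copy locus carrying two alleles.
#'
#' @return a [ystr_panel()].
#' @export
powerplex_y23 <- function() {
  ystr_panel(
    loci = c("DYS576", "DYS389I", "DYS448", "DYS389II", "DYS19", "DYS391",
             "DYS481", "DYS549", "DYS533", "DYS438", "DYS437", "DYS570",
             "DYS635", "DYS390", "DYS439", "DYS392", "DYS643", "DYS393",
             "DYS458", "DYS385", "DYS456", "YGATAH4"),
    multi_copy = "DYS385")
}

format_alleles <- function(a) paste(format(sort(a), trim = TRUE), collapse = ",")

parse_alleles <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell) || cell %in% c("NA", ".")) return(NULL)
  vals <- suppressWarnings(as.numeric(strsplit(cell, ",")[[1]]))
  if (anyNA(vals))
    kinlr_stop("kinlr_bad_allele", "non-numeric allele value: %s", cell)
  if (any(vals <= 0))
    kinlr_stop("kinlr_bad_allele", "allele values must be positive: %s", cell)
  sort(vals)
}

#' Y-STR haplotype
#'
#' @param alleles named list (or vector) mapping locus name to allele
#'   value(s): a single repeat count (possibly fractional, e.g. 13.2) for
#'   single-copy loci, a sorted numeric multiset for multi-copy loci.
#'   A locus may be explicitly missing (`NULL`); it is then excluded from
#'   comparisons.
#' @param panel a [ystr_panel()].
#' @param id optional sample id.
#' @param haplogroup optional haplogroup label (e.g. `"R1b-U152"`,
#'   `"I-M170"`, `"G-P287"`); treated as an opaque string, matched on the
#'   top-level clade token before the hyphen.
#' @return object of class `ystr_haplotype`.
#' @export
ystr_haplotype <- function(alleles, panel = powerplex_y23(), id = NA_character_,
                           haplogroup = NA_character_) {
  stopifnot(inherits(panel, "ystr_panel"))
  if (!is.list(alleles)) alleles <- as.list(alleles)
  unknown <- setdiff(names(alleles), panel$loci)
  if (length(unknown) > 0L)
    kinlr_stop("kinlr_unknown_locus", "allele(s) at loci not in panel: %s",
               paste(unknown, collapse = ", "))
  out <- stats::setNames(vector("list", length(panel$loci)), panel$loci)
  for (loc in names(alleles)) {
    v <- alleles[[loc]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) next
    v <- sort(as.numeric(v))
    if (anyNA(v) || any(v <= 0))
      kinlr_stop("kinlr_bad_allele", "invalid allele value(s) at %s", loc)
    out[[loc]] <- v
  }
  structure(list(id = as.character(id), panel = panel, alleles = out,
                 haplogroup = as.character(haplogroup)),
            class = "ystr_haplotype")
}

#' @export
print.ystr_haplotype <- function(x, ...) {
  typed <- sum(!vapply(x$alleles, is.null, logical(1)))
  cat(sprintf("<ystr_haplotype> %s: %d/%d loci typed%s\n",
              if (is.na(x$id)) "(unnamed)" else x$id,
              typed, length(x$panel$loci),
              if (is.na(x$haplogroup)) "" else paste0(", ", x$haplogroup)))
  invisible(x)
}

clade_token <- function(label) sub("-.*$", "", label)

#' Read / write a wide Y-STR haplotype table
#'
#' Tab-separated, one row per sample: an `id` column, an optional
#' `haplogroup` column, and one column per panel locus; multi-copy alleles
#' comma-separated.  The writer emits this exact dialect, so write/read
#' round-trips are byte-identical.
#'
#' @param path file path.
#' @param panel a [ystr_panel()]; defaults to the locus columns found in the
#'   file (in file order, with DYS385 multi-copy if present).
#' @return `read_ystr_table()` returns a list of [ystr_haplotype()];
#'   the writer returns `path` invisibly.
#' @export
read_ystr_table <- function(path, panel = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", na.strings = NULL,
                          check.names = FALSE)
  if (!"id" %in% names(df))
    kinlr_stop("kinlr_bad_table", "Y-STR table lacks an 'id' column")
  locus_cols <- setdiff(names(df), c("id", "haplogroup"))
  if (is.null(panel)) {
    panel <- ystr_panel(locus_cols,
                        multi_copy = intersect("DYS385", locus_cols))
  } else {
    stopifnot(inherits(panel, "ystr_panel"))
    missing_cols <- setdiff(panel$loci, locus_cols)
    if (length(missing_cols) > 0L)
      kinlr_stop("kinlr_bad_table", "missing panel locus column(s): %s",
                 paste(missing_cols, collapse = ", "))
    extra <- setdiff(locus_cols, panel$loci)
    if (length(extra) > 0L)
      kinlr_stop("kinlr_unknown_locus", "locus column(s) not in panel: %s",
                 paste(extra, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    alleles <- lapply(stats::setNames(panel$loci, panel$loci),
                      function(loc) parse_alleles(df[[loc]][i]))
    ystr_haplotype(alleles, panel = panel, id = df$id[i],
                   haplogroup = if ("haplogroup" %in% names(df))
                     (if (nzchar(df$haplogroup[i])) df$haplogroup[i]
                      else NA_character_) else NA_character_)
  })
}

#' @rdname read_ystr_table
#' @param haps list of [ystr_haplotype()] sharing one panel.
#' @export
write_ystr_table <- function(haps, path) {
  stopifnot(length(haps) >= 1L)
  panel <- haps[[1L]]$panel
  rows <- lapply(haps, function(h) {
    stopifnot(identical(h$panel$loci, panel$loci))
    cells <- vapply(panel$loci, function(loc) {
      v <- h$alleles[[loc]]
      if (is.null(v)) "" else format_alleles(v)
    }, "")
    c(id = h$id, haplogroup = if (is.na(h$haplogroup)) "" else h$haplogroup,
      cells)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Compare two Y-STR haplotypes locus by locus
#'
#' Loci missing in either haplotype are excluded from the comparison; a
#' compared locus mismatches if the allele values differ (multiset inequality
#' for multi-copy loci).
#'
#' @param h1,h2 [ystr_haplotype()] on the same panel.
#' @return list with `mismatch_loci` (character), `mismatch_count`,
#'   `compared` (number of loci typed in both).
#' @export
ystr_compare <- function(h1, h2) {
  stopifnot(inherits(h1, "ystr_haplotype"), inherits(h2, "ystr_haplotype"))
  if (!identical(h1$panel$loci, h2$panel$loci))
    kinlr_stop("kinlr_panel_mismatch", "haplotypes are on different panels")
  loci <- h1$panel$loci
  both <- vapply(loci, function(loc)
    !is.null(h1$alleles[[loc]]) && !is.null(h2$alleles[[loc]]), logical(1))
  mm <- vapply(loci[both], function(loc)
    !identical(h1$alleles[[loc]], h2$alleles[[loc]]), logical(1))
  list(mismatch_loci = loci[both][mm],
       mismatch_count = sum(mm),
       compared = sum(both))
}

#' Partition haplotypes into a consistent patriline core and exclusions
#'
#' Flags individuals who cannot belong to the claimed patrilinear group.
#' Haplogroup discordance takes precedence: an individual whose top-level
#' clade token differs from the modal clade among labelled samples is
#' excluded outright (a different haplogroup cannot arise by STR mutation
#' within the genealogical time frame; it indicates a false-paternity event).
#' Among clade-consistent (or unlabelled) individuals, one is additionally
#' excluded if its minimum pairwise mismatch count against modal-clade
#' members exceeds `max_mismatch`.
#'
#' @param haps list of >= 2 [ystr_haplotype()].
#' @param max_mismatch maximum tolerated STR mismatch count; default 10% of
#'   compared loci, rounded up -- an explicit heuristic allowing for stepwise
#'   mutation over long genealogies.
#' @return list with `core` and `excluded`: character vectors of ids.
#' @export
partition_patriline <- function(haps, max_mismatch = NULL) {
  if (length(haps) < 2L)
    kinlr_stop("kinlr_bad_argument", "need at least two haplotypes")
  ids <- vapply(seq_along(haps), function(i) {
    id <- haps[[i]]$id
    if (is.na(id)) sprintf("sample%d", i) else id
  }, "")
  labels <- vapply(haps, function(h) h$haplogroup, "")
  has_label <- !is.na(labels)
  if (!any(has_label) && is.null(max_mismatch))
    kinlr_stop("kinlr_bad_argument",
               "no haplogroup labels present and max_mismatch unset")
  excluded <- logical(length(haps))
  if (any(has_label)) {
    clades <- clade_token(labels[has_label])
    modal <- names(which.max(table(clades)))
    excluded[has_label][clades != modal] <- TRUE
    modal_members <- which(has_label)[clades == modal]
  } else {
    modal_members <- seq_along(haps)
  }
  # STR screening applies to everyone not already excluded by haplogroup,
  # including modal-clade members themselves.
  for (i in seq_along(haps)) {
    if (excluded[i]) next
    others <- setdiff(modal_members, i)
    if (length(others) == 0L) next
    cmp <- lapply(others, function(j) ystr_compare(haps[[i]], haps[[j]]))
    counts <- vapply(cmp, `[[`, 0L, "mismatch_count")
    compared <- vapply(cmp, `[[`, 0L, "compared")
    lim <- if (is.null(max_mismatch))
      ceiling(0.10 * compared[which.min(counts)]) else max_mismatch
    if (min(counts) > lim) excluded[i] <- TRUE
  }
  list(core = ids[!excluded], excluded = ids[excluded])
}

#' Probability of at least one false-paternity event
#'
#' With independent per-link false-paternity probability `r` over `m`
#' recorded father-son links, the probability that at least one link is
#' broken is `1 - (1 - r)^m`.  This is the exposure that explains a
#' Y-chromosome mismatch between remains and genealogically identified
#' patrilinear relatives.
#'
#' @param r per-link false-paternity probability, in `[0, 1]`.
#' @param m number of father-son links (non-negative integer).
#' @return probability in `[0, 1]`.
#' @export
false_paternity_prob <- function(r, m) {
  if (!is_prob(r))
    kinlr_stop("kinlr_bad_argument", "r must lie in [0, 1]")
  if (!is_count(m))
    kinlr_stop("kinlr_bad_argument", "m must be a non-negative integer")
  1 - (1 - r)^m
}

#' Y-chromosome evidence likelihood ratio for an observed non-match
#'
#' Contract: this LR applies only when the remains' Y-haplotype does NOT
#' match the patriline.  Under H1 (remains are the target) the non-match
#' requires at least one false-paternity event among the `m` links, with
#' probability `1 - (1 - r)^m`; under H2 any Y-haplotype would be a draw
#' from the population either way, and its population frequency is the same
#' under both hypotheses, so it cancels.  Hence LR = the false-paternity
#' exposure probability, a value below 1 (limited evidence against H1).
#'
#' @inheritParams false_paternity_prob
#' @return likelihood ratio in `[0, 1]`.
#' @export
y_lr <- function(r, m) false_paternity_prob(r, m)
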