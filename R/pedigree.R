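#' Construct a pedigree from a table of individuals
#'
#' A pedigree is a collection of individuals with optional father and mother
#' links, used here exclusively for uniparental-lineage queries: matriline and
#' patriline paths, meiosis counts between relatives, and matrilineal kinship
#' networks (the set of individuals expected to share an inherited mtDNA type).
#'
#' @param df data frame with columns `id`, `father_id`, `mother_id`, `sex`
#'   and optionally `label`, `birth_year`, `death_year`.  Following PED
#'   convention the string `"0"` (or `NA`/empty) denotes an unknown parent.
#'   `sex` is one of `"male"`, `"female"`, `"unknown"` (`"M"`/`"F"`/`"1"`/
#'   `"2"`/`"0"` are accepted and canonicalised).
#' @return An object of class `pedigree`: a data frame of validated
#'   individuals keyed by `id`.
#' @details Validation failures raise classed conditions so each failure mode
#'   is programmatically distinguishable: `kinlr_duplicate_id`,
#'   `kinlr_dangling_parent`, `kinlr_cycle`, `kinlr_sex_role`.  An individual
#'   of unknown sex appearing as a parent is allowed with a warning
#'   (`kinlr_sex_unknown_parent`); historical genealogies are incomplete and
#'   the link itself implies the role.
#' @seealso [read_pedigree()], [matriline()], [meioses_between()]
#' @export
pedigree <- function(df) {
  required <- c("id", "father_id", "mother_id", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    kinlr_stop("kinlr_bad_table", "pedigree table lacks column(s): %s",
               paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  df$father_id <- canon_parent(df$father_id)
  df$mother_id <- canon_parent(df$mother_id)
  df$sex <- canon_sex(df$sex)
  if (!"label" %in% names(df)) df$label <- df$id
  for (col in c("birth_year", "death_year"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_

  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L)
    kinlr_stop("kinlr_duplicate_id", "duplicate individual id(s): %s",
               paste(unique(dup), collapse = ", "))

  known <- df$id
  for (side in c("father_id", "mother_id")) {
    ref <- df[[side]]
    bad <- !is.na(ref) & !(ref %in% known)
    if (any(bad))
      kinlr_stop("kinlr_dangling_parent",
                 "%s reference(s) to unknown individual(s): %s",
                 side, paste(unique(ref[bad]), collapse = ", "))
  }

  # Sex consistency of parent roles (unknown sex warns, not errors).
  sex_of <- stats::setNames(df$sex, df$id)
  fathers <- unique(stats::na.omit(df$father_id))
  mothers <- unique(stats::na.omit(df$mother_id))
  if (any(sex_of[fathers] == "female"))
    kinlr_stop("kinlr_sex_role", "female individual(s) referenced as father: %s",
               paste(fathers[sex_of[fathers] == "female"], collapse = ", "))
  if (any(sex_of[mothers] == "male"))
    kinlr_stop("kinlr_sex_role", "male individual(s) referenced as mother: %s",
               paste(mothers[sex_of[mothers] == "male"], collapse = ", "))
  unk <- c(fathers[sex_of[fathers] == "unknown"],
           mothers[sex_of[mothers] == "unknown"])
  if (length(unk) > 0L)
    kinlr_warn("kinlr_sex_unknown_parent",
               "individual(s) of unknown sex used as parent: %s",
               paste(unk, collapse = ", "))

  check_acyclic(df)
  rownames(df) <- df$id
  class(df) <- c("pedigree", "data.frame")
  df
}

canon_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("0", "", "NA")] <- NA_character_
  x
}

canon_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "2")] <- "female"
  out[x %in% c("unknown", "u", "0", "", NA)] <- "unknown"
  out[is.na(x)] <- "unknown"
  if (anyNA(out))
    kinlr_stop("kinlr_bad_table", "unrecognised sex code(s): %s",
               paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# Cycle detection by iterated leaf-stripping (Kahn): individuals whose parents
# have all been removed are deleted in rounds; leftovers lie on a cycle.
check_acyclic <- function(df) {
  remaining <- df$id
  parent <- rbind(cbind(df$id, df$father_id), cbind(df$id, df$mother_id))
  parent <- parent[!is.na(parent[, 2L]), , drop = FALSE]
  repeat {
    has_parent <- remaining %in% parent[, 1L][parent[, 2L] %in% remaining]
    if (!any(has_parent)) return(invisible(TRUE))
    if (all(has_parent))
      kinlr_stop("kinlr_cycle", "pedigree contains a cycle involving: %s",
                 paste(remaining, collapse = ", "))
    remaining <- remaining[has_parent]
  }
}

#' Read / write a PED-like pedigree table
#'
#' Tab-separated with a header row; columns `id`, `father_id`, `mother_id`,
#' `sex` and optionally `label`, `birth_year`, `death_year`; `"0"` marks an
#' unknown parent.  `write_pedigree()` emits exactly this dialect so that
#' write/read round-trips are byte-identical.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a [pedigree()]; `write_pedigree()`
#'   returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  pedigree(df)
}

#' @rdname read_pedigree
#' @param ped a `pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  out$father_id[is.na(out$father_id)] <- "0"
  out$mother_id[is.na(out$mother_id)] <- "0"
  keep <- c("id", "father_id", "mother_id", "sex", "label",
            "birth_year", "death_year")
  out <- out[, keep]
  out$birth_year[is.na(out$birth_year)] <- "0"
  out$death_year[is.na(out$death_year)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals (%d male, %d female, %d unknown)\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female"),
              sum(x$sex == "unknown")))
  founders <- sum(is.na(x$father_id) & is.na(x$mother_id))
  cat(sprintf("  founders (no recorded parent): %d\n", founders))
  invisible(x)
}

check_id <- function(ped, id) {
  if (!is_string(id) || !(id %in% ped$id))
    kinlr_stop("kinlr_unknown_id", "unknown individual id: %s", id)
  id
}

uniline <- function(ped, id, link) {
  check_id(ped, id)
  parent <- stats::setNames(ped[[link]], ped$id)
  out <- character(0)
  cur <- id
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent[[cur]]
  }
  out
}

#' Uniparental ancestor lines
#'
#' `matriline()` returns the unbroken mother line starting at `id`
#' (`id`, mother, mother's mother, ...) up to the most distant recorded
#' ancestress; `patriline()` the analogous father line.  Absent mutation,
#' every individual on a matriline carries the founder's mtDNA type and every
#' individual on a patriline (absent false paternity) the founder's
#' Y-chromosome type.
#'
#' @param ped a [pedigree()].
#' @param id individual id.
#' @return character vector of ids, first element `id` itself.
#' @export
matriline <- function(ped, id) uniline(ped, id, "mother_id")

#' @rdname matriline
#' @export
patriline <- function(ped, id) uniline(ped, id, "father_id")

#' Count meioses separating two individuals along a uniparental line
#'
#' Finds the most recent common ancestor on the chosen uniparental line and
#' returns the number of parent-child transmissions (meioses) along the
#' connecting path, i.e. the sum of the generation counts from each individual
#' up to that ancestor.  If one individual is the other's lineal ancestor the
#' direct generation count is returned.  When multiple common uniparental
#' ancestors exist the most recent (minimal total meioses) is used, matching
#' the most-recent-common-ancestor convention implicit in cousin naming.
#'
#' @inheritParams matriline
#' @param a,b individual ids.
#' @param lineage `"matrilineal"` or `"patrilineal"`.
#' @return integer meiosis count; `NA_integer_` if `a` and `b` share no
#'   recorded ancestor on this lineage (the "unrelated on this lineage"
#'   outcome, deliberately not an error).
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("gm", "m1", "m2", "a", "b"),
#'   father_id = "0",
#'   mother_id = c("0", "gm", "gm", "m1", "m2"),
#'   sex = c("female", "female", "female", "female", "female")))
#' meioses_between(ped, "a", "b", "matrilineal")  # first cousins: 4
#' @export
meioses_between <- function(ped, a, b, lineage = c("matrilineal", "patrilineal")) {
  lineage <- match.arg(lineage)
  link <- if (lineage == "matrilineal") "mother_id" else "father_id"
  la <- uniline(ped, a, link)
  lb <- uniline(ped, b, link)
  common <- intersect(la, lb)
  if (length(common) == 0L) return(NA_integer_)
  # Uniparental lines are chains, so common ancestors form a shared suffix;
  # the most recent one minimises the total path length.
  steps <- match(common, la) + match(common, lb) - 2L
  as.integer(min(steps))
}

#' Cousin terminology from generation counts
#'
#' Converts the generation counts of two individuals below their most recent
#' common ancestor into standard cousin terminology.  With `g_a <= g_b`
#' (swapped internally): degree `g_a - 1`, removal `g_b - g_a`, and total
#' meioses `g_a + g_b`.  Siblings are (1, 1): 0th degree, 0 removed, 2
#' meioses.
#'
#' @param g_a,g_b positive generation counts from each individual up to the
#'   common ancestor.
#' @return object of class `cousin_terms`: list with `degree`, `removed`,
#'   `meioses` (satisfying `meioses == 2 * (degree + 1) + removed`).
#' @examples
#' cousin_terms(15, 17)  # 14th cousins twice removed, 32 meioses
#' @export
cousin_terms <- function(g_a, g_b) {
  if (!is_count(g_a, min = 1L) || !is_count(g_b, min = 1L))
    kinlr_stop("kinlr_bad_argument",
               "generation counts must be positive integers")
  lo <- min(g_a, g_b); hi <- max(g_a, g_b)
  structure(list(degree = as.integer(lo - 1L),
                 removed = as.integer(hi - lo),
                 meioses = as.integer(lo + hi)),
            class = "cousin_terms")
}

#' @export
print.cousin_terms <- function(x, ...) {
  ord <- function(n) {
    if (n %% 100 %in% 11:13) return(paste0(n, "th"))
    paste0(n, switch(as.character(n %% 10), "1" = "st", "2" = "nd",
                     "3" = "rd", "th"))
  }
  rem <- switch(as.character(min(x$removed, 3L)),
                "0" = "", "1" = ", once removed", "2" = ", twice removed",
                sprintf(", %d times removed", x$removed))
  if (x$degree == 0L) {
    cat(sprintf("siblings%s (%d meioses)\n", rem, x$meioses))
  } else {
    cat(sprintf("%s cousins%s (%d meioses)\n", ord(x$degree), rem, x$meioses))
  }
  invisible(x)
}

#' Matrilineal kinship network
#'
#' All individuals in the pedigree sharing `id`'s matrilineal founder
#' ancestress -- i.e. everyone expected to carry the same inherited mtDNA type
#' absent mutation, including `id` itself.  Used to rule out contemporaries
#' who would share the target's mtDNA by descent.
#'
#' @inheritParams matriline
#' @return character vector of ids (unordered set).
#' @export
matrilineal_network <- function(ped, id) {
  check_id(ped, id)
  root <- function(i) {
    line <- uniline(ped, i, "mother_id")
    line[length(line)]
  }
  target_root <- root(id)
  ped$id[vapply(ped$id, root, character(1)) == target_root]
}
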