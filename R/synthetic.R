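#' Simulation configuration
#'
#' Bundles every tunable of the forward simulator: pedigree shape, per-link
#' false-paternity rate, per-meiosis mtDNA mutation probability, per-locus
#' Y-STR stepwise mutation rate, and the population haplotype frequency
#' spectrum from which founders and database records are drawn.
#'
#' The defaults are the study conditions of the identification framework:
#' `fp_rate = 0.009` (a conservative genealogical false-paternity rate),
#' `mt_mu = 10/327` (10 control-region mutations observed in 327
#' pedigree-transmission generations), `str_rate = 2e-3` per locus per
#' meiosis (typical Y-STR stepwise rate), a database of size 1,831 over the
#' control-region ranges 16093-16320 and 73-188, and case lineages of 19
#' meioses (matriline) and 19 father-son links (patriline).
#'
#' @param seed integer RNG seed; recorded in every output.
#' @param generations number of generation levels in simulated pedigrees
#'   (founders are level 1; `generations = 1` means founders only).
#' @param founder_couples number of founder couples.
#' @param mean_offspring mean offspring per couple (Poisson).
#' @param max_couples cap on reproducing couples per generation level.
#' @param fp_rate per-link false-paternity probability `r`.
#' @param mt_mu per-meiosis mtDNA control-region mutation probability.
#' @param str_rate per-locus per-meiosis Y-STR mutation probability.
#' @param db_size population database size `n`.
#' @param db_alpha concentration of the stick-breaking haplotype frequency
#'   spectrum (small = one dominant haplotype; large = many rare ones).
#' @param panel Y-STR panel ([ystr_panel()]).
#' @param ranges declared mtDNA ranges ([mt_ranges()]).
#' @param case_mt_meioses,case_y_links meioses separating skeleton and
#'   matrilineal relative / father-son links to the patrilinear relatives in
#'   generated cases.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, generations = 5L, founder_couples = 3L,
                       mean_offspring = 2, max_couples = 25L,
                       fp_rate = 0.009, mt_mu = 10 / 327, str_rate = 2e-3,
                       db_size = 1831L, db_alpha = 5,
                       panel = powerplex_y23(),
                       ranges = mt_ranges("16093-16320 73-188"),
                       case_mt_meioses = 19L, case_y_links = 19L) {
  if (!is_count(generations, min = 1L))
    kinlr_stop("kinlr_bad_argument", "generations must be a positive integer")
  if (!is_count(founder_couples, min = 1L) || !is_count(max_couples, min = 1L))
    kinlr_stop("kinlr_bad_argument", "counts must be positive integers")
  if (!is.numeric(mean_offspring) || mean_offspring <= 0)
    kinlr_stop("kinlr_bad_argument", "mean_offspring must be positive")
  for (p in c(fp_rate, mt_mu, str_rate))
    if (!is_prob(p)) kinlr_stop("kinlr_bad_argument",
                                "rates must be probabilities in [0, 1]")
  if (!is_count(db_size))
    kinlr_stop("kinlr_bad_argument", "db_size must be a non-negative integer")
  if (!is.numeric(db_alpha) || db_alpha <= 0)
    kinlr_stop("kinlr_bad_argument", "db_alpha must be positive")
  if (!is_count(case_mt_meioses, 1L) || !is_count(case_y_links, 1L))
    kinlr_stop("kinlr_bad_argument", "case lineage lengths must be positive")
  structure(list(seed = as.integer(seed), generations = as.integer(generations),
                 founder_couples = as.integer(founder_couples),
                 mean_offspring = mean_offspring,
                 max_couples = as.integer(max_couples),
                 fp_rate = fp_rate, mt_mu = mt_mu, str_rate = str_rate,
                 db_size = as.integer(db_size), db_alpha = db_alpha,
                 panel = panel, ranges = mt_ranges(ranges),
                 case_mt_meioses = as.integer(case_mt_meioses),
                 case_y_links = as.integer(case_y_links)),
            class = "sim_config")
}

#' Simulate a pedigree
#'
#' Generates an acyclic multi-generation pedigree.  Two lineages are
#' guaranteed to persist to the deepest level so that uniparental queries
#' always have a full-depth line to follow: a daughter chain (ids prefixed
#' `MAT`) and a son chain (ids prefixed `PAT`), each member married to an
#' immigrant founder spouse.  Collateral couples reproduce with
#' Poisson(`mean_offspring`) offspring, capped at `max_couples` reproducing
#' couples per level.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed override.
#' @return a [pedigree()] with attributes `matriline_ids` and
#'   `patriline_ids` (the guaranteed chains, founder first).
#' @export
simulate_pedigree <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    rows <- list()
    add <- function(id, father, mother, sex) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, father_id = father %||% NA_character_,
        mother_id = mother %||% NA_character_, sex = sex)
    }
    mat_chain <- "MAT-G1"; pat_chain <- "PAT-G1"
    add("MAT-G1", NULL, NULL, "female")
    add("MAT-G1-SP", NULL, NULL, "male")
    add("PAT-G1", NULL, NULL, "male")
    add("PAT-G1-SP", NULL, NULL, "female")
    # couples: list of c(father, mother)
    couples <- list(c("MAT-G1-SP", "MAT-G1"), c("PAT-G1", "PAT-G1-SP"))
    for (i in seq_len(cfg$founder_couples)) {
      add(sprintf("G1-C%d-M", i), NULL, NULL, "male")
      add(sprintf("G1-C%d-F", i), NULL, NULL, "female")
      couples[[length(couples) + 1L]] <- c(sprintf("G1-C%d-M", i),
                                           sprintf("G1-C%d-F", i))
    }
    if (cfg$generations > 1L) for (g in 2:cfg$generations) {
      next_couples <- list()
      kid <- 0L
      # guaranteed chains: one daughter on the MAT line, one son on the PAT line
      mat_id <- sprintf("MAT-G%d", g); mat_sp <- sprintf("MAT-G%d-SP", g)
      add(mat_id, couples[[1L]][1L], couples[[1L]][2L], "female")
      add(mat_sp, NULL, NULL, "male")
      next_couples[[1L]] <- c(mat_sp, mat_id)
      pat_id <- sprintf("PAT-G%d", g); pat_sp <- sprintf("PAT-G%d-SP", g)
      add(pat_id, couples[[2L]][1L], couples[[2L]][2L], "male")
      add(pat_sp, NULL, NULL, "female")
      next_couples[[2L]] <- c(pat_id, pat_sp)
      mat_chain <- c(mat_chain, mat_id); pat_chain <- c(pat_chain, pat_id)
      for (ci in seq_along(couples)) {
        n_off <- stats::rpois(1L, cfg$mean_offspring)
        if (n_off == 0L) next
        for (k in seq_len(n_off)) {
          kid <- kid + 1L
          sex <- if (stats::runif(1) < 0.5) "male" else "female"
          id <- sprintf("G%d-I%d", g, kid)
          add(id, couples[[ci]][1L], couples[[ci]][2L], sex)
          if (length(next_couples) < cfg$max_couples) {
            sp <- sprintf("G%d-S%d", g, kid)
            add(sp, NULL, NULL, if (sex == "male") "female" else "male")
            next_couples[[length(next_couples) + 1L]] <-
              if (sex == "male") c(id, sp) else c(sp, id)
          }
        }
      }
      couples <- next_couples
    }
    ped <- pedigree(do.call(rbind, rows))
    attr(ped, "matriline_ids") <- mat_chain
    attr(ped, "patriline_ids") <- pat_chain
    attr(ped, "seed") <- as.integer(seed)
    ped
  })
}

# ---- population haplotype spectrum ------------------------------------------

# Truncated stick-breaking (GEM) weights with concentration alpha.
stick_breaking <- function(alpha, max_k = 500L, tol = 1e-8) {
  v <- stats::rbeta(max_k, 1, alpha)
  w <- v * cumprod(c(1, 1 - v[-max_k]))
  keep <- max(which(cumsum(w) < 1 - tol), 1L)
  w <- w[seq_len(keep)]
  w / sum(w)
}

Y_CLADES <- c("R1b-U152", "I-M170", "G-P287", "J2-M172", "E1b-M35",
              "R1a-M198", "N-M231")

#' Population haplotype spectrum
#'
#' Draws the latent population of mtDNA and Y haplotypes, with stick-breaking
#' frequency weights (concentration `db_alpha`), from which founders,
#' false-paternity donors and database records are sampled.  Deterministic
#' given the seed.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed override.
#' @return object of class `hap_spectrum`: list with `mt` (list of
#'   [mt_haplotype()]), `y` (list of [ystr_haplotype()]), `freqs`.
#' @export
population_spectrum <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    freqs <- stick_breaking(cfg$db_alpha)
    k <- length(freqs)
    positions <- unlist(lapply(seq_len(nrow(cfg$ranges)), function(i)
      cfg$ranges$start[i]:cfg$ranges$end[i]))
    mt <- lapply(seq_len(k), function(i) {
      n_var <- stats::rpois(1L, 4) + 1L
      pos <- sample(positions, min(n_var, length(positions)))
      mt_haplotype(sprintf("%d%s", pos,
                           sample(c("A", "C", "G", "T"), length(pos),
                                  replace = TRUE)),
                   cfg$ranges, max_pos = max(cfg$ranges$end))
    })
    y <- lapply(seq_len(k), function(i) {
      alleles <- lapply(stats::setNames(cfg$panel$loci, cfg$panel$loci),
                        function(loc) {
                          n_copy <- if (loc %in% cfg$panel$multi_copy) 2L else 1L
                          sort(sample(10:24, n_copy, replace = TRUE))
                        })
      ystr_haplotype(alleles, panel = cfg$panel,
                     id = sprintf("POP%d", i),
                     haplogroup = sample(Y_CLADES, 1L))
    })
    structure(list(freqs = freqs, mt = mt, y = y), class = "hap_spectrum")
  })
}

#' Sample a population haplotype database
#'
#' Draws `cfg$db_size` records from the spectrum's frequency weights.  The
#' true population frequency of every sampled haplotype is retained so
#' estimator behaviour (e.g. the conservatism of the pseudocount rule) can be
#' scored against ground truth.
#'
#' @param cfg a [sim_config()].
#' @param spectrum a [population_spectrum()] (generated from `cfg` if
#'   omitted).
#' @param seed optional seed override.
#' @return list with `db` (an [mt_db()]), `hap_index` (spectrum index per
#'   record), `true_freqs` (per spectrum haplotype), and `seed`.
#' @export
sample_database <- function(cfg, spectrum = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(spectrum)) spectrum <- population_spectrum(cfg, seed = seed)
  with_seed(seed + 1L, {
    n <- cfg$db_size
    idx <- if (n > 0L)
      sample.int(length(spectrum$freqs), n, replace = TRUE,
                 prob = spectrum$freqs) else integer(0)
    db <- mt_db(if (n > 0L) sprintf("DB%05d", seq_len(n)) else character(0),
                spectrum$mt[idx])
    list(db = db, hap_index = idx, true_freqs = spectrum$freqs,
         seed = as.integer(seed))
  })
}

mutate_mt <- function(hap, ranges) {
  positions <- unlist(lapply(seq_len(nrow(ranges)), function(i)
    ranges$start[i]:ranges$end[i]))
  pos <- sample(positions, 1L)
  existing <- grepl(sprintf("^%d[ACGT]$", pos), hap$variants)
  cur_base <- if (any(existing)) sub("^[0-9]+", "", hap$variants[existing]) else ""
  new_base <- sample(setdiff(c("A", "C", "G", "T"), cur_base), 1L)
  variants <- c(hap$variants[!existing], sprintf("%d%s", pos, new_base))
  list(hap = mt_haplotype(variants, hap$ranges, max_pos = max(hap$ranges$end)),
       position = pos)
}

mutate_y <- function(hap, str_rate) {
  events <- list()
  loci <- hap$panel$loci
  hit <- stats::runif(length(loci)) < str_rate
  for (loc in loci[hit]) {
    v <- hap$alleles[[loc]]
    if (is.null(v)) next
    i <- sample.int(length(v), 1L)
    step <- sample(c(-1, 1), 1L)
    v[i] <- max(1, v[i] + step)
    hap$alleles[[loc]] <- sort(v)
    events[[length(events) + 1L]] <- data.frame(locus = loc, step = step)
  }
  list(hap = hap, events = events)
}

#' Transmit uniparental markers down a pedigree
#'
#' Every individual receives mtDNA from their recorded mother, mutated with
#' probability `mt_mu` per meiosis (at most one event per meiosis: a single
#' uniformly chosen in-range position changes to a uniformly chosen different
#' base -- the simplest model consistent with a per-meiosis rate, and the one
#' whose perfect-transmission probability is exactly `(1 - mu)^m`).  Every
#' male receives a Y-STR haplotype from his recorded father with probability
#' `1 - fp_rate`; otherwise (a false-paternity event) from a random male of
#' the population spectrum, which usually changes the haplogroup label.
#' Each transmitted Y locus then mutates stepwise (+/-1 repeat,
#' equiprobable) with probability `str_rate`.  Founders draw from the
#' spectrum.  The truth record lists every false-paternity link and mutation
#' event.
#'
#' @param ped a [pedigree()].
#' @param cfg a [sim_config()].
#' @param spectrum optional [population_spectrum()].
#' @param seed optional seed override.
#' @return object of class `marker_transmission`: list with `mt` (named list
#'   of [mt_haplotype()]), `y` (named list of [ystr_haplotype()], males
#'   only), and `truth` (list: `fp_links`, `mt_mutations`, `str_mutations`
#'   data frames; `founder_mt_index`; `seed`).
#' @export
transmit_markers <- function(ped, cfg, spectrum = NULL, seed = cfg$seed) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  if (is.null(spectrum)) spectrum <- population_spectrum(cfg, seed = seed)
  with_seed(seed + 2L, {
    mt <- list(); y <- list()
    founder_mt_index <- integer(0)
    fp_links <- list(); mt_mut <- list(); str_mut <- list()
    # process in dependency order: parents before children
    order <- character(0); remaining <- ped$id
    while (length(remaining) > 0L) {
      ready <- vapply(remaining, function(i) {
        f <- ped[i, "father_id"]; m <- ped[i, "mother_id"]
        (is.na(f) || f %in% order) && (is.na(m) || m %in% order)
      }, logical(1))
      order <- c(order, remaining[ready])
      remaining <- remaining[!ready]
    }
    draw <- function() sample.int(length(spectrum$freqs), 1L,
                                  prob = spectrum$freqs)
    for (id in order) {
      mo <- ped[id, "mother_id"]; fa <- ped[id, "father_id"]
      if (is.na(mo)) {
        i <- draw()
        mt[[id]] <- spectrum$mt[[i]]
        founder_mt_index[[id]] <- i
      } else {
        h <- mt[[mo]]
        if (stats::runif(1) < cfg$mt_mu) {
          res <- mutate_mt(h, cfg$ranges)
          h <- res$hap
          mt_mut[[length(mt_mut) + 1L]] <- data.frame(id = id,
                                                      position = res$position)
        }
        mt[[id]] <- h
      }
      if (ped[id, "sex"] == "male") {
        if (is.na(fa)) {
          h <- spectrum$y[[draw()]]
        } else if (stats::runif(1) < cfg$fp_rate) {
          h <- spectrum$y[[draw()]]
          fp_links[[length(fp_links) + 1L]] <-
            data.frame(child = id, recorded_father = fa)
        } else {
          h <- y[[fa]]
        }
        res <- mutate_y(h, cfg$str_rate)
        h <- res$hap
        for (e in res$events)
          str_mut[[length(str_mut) + 1L]] <- cbind(data.frame(id = id), e)
        h$id <- id
        y[[id]] <- h
      }
    }
    bind <- function(lst, proto) if (length(lst) > 0L) do.call(rbind, lst) else proto
    structure(list(
      mt = mt, y = y,
      truth = list(
        fp_links = bind(fp_links, data.frame(child = character(0),
                                             recorded_father = character(0))),
        mt_mutations = bind(mt_mut, data.frame(id = character(0),
                                               position = integer(0))),
        str_mutations = bind(str_mut, data.frame(id = character(0),
                                                 locus = character(0),
                                                 step = numeric(0))),
        founder_mt_index = founder_mt_index,
        seed = as.integer(seed))),
      class = "marker_transmission")
  })
}

# Case pedigree mirroring the study layout: the target is a child of the
# founder ancestress / patriarch; the living relatives sit at the bottom of a
# second branch, `m - 1` generations below, so that target and relative are
# separated by exactly `m` meioses (matriline) / `m` father-son links
# (patriline).
case_pedigree <- function(mt_meioses, y_links) {
  rows <- list()
  add <- function(id, father, mother, sex)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father_id = father %||% NA_character_,
      mother_id = mother %||% NA_character_, sex = sex)
  add("ANCESTRESS", NULL, NULL, "female")
  add("PATRIARCH", NULL, NULL, "male")
  add("TARGET", "PATRIARCH", "ANCESTRESS", "male")
  prev <- "ANCESTRESS"
  for (g in seq_len(mt_meioses - 1L)) {
    id <- sprintf("MATREL-G%d", g)
    add(id, NULL, prev, if (g == mt_meioses - 1L) "male" else "female")
    prev <- id
  }
  mat_relative <- prev
  prev <- "PATRIARCH"
  for (g in seq_len(y_links - 1L)) {
    id <- sprintf("PATREL-G%d", g)
    add(id, prev, NULL, "male")
    prev <- id
  }
  pat_relative <- prev
  ped <- suppressWarnings(pedigree(do.call(rbind, rows)))
  attr(ped, "target") <- "TARGET"
  attr(ped, "mat_relative") <- mat_relative
  attr(ped, "pat_relative") <- pat_relative
  ped
}

#' Generate a complete synthetic identification case
#'
#' Builds a case bundle with known ground truth: a pedigree placing the
#' target `cfg$case_mt_meioses` meioses from a living matrilineal relative
#' and `cfg$case_y_links` father-son links from a living patrilinear
#' relative; marker transmission down both branches with the configured
#' false-paternity and mutation rates; a population database sample; and the
#' skeleton's profiles -- copied from the target individual under H1, or
#' drawn from the unrelated population under H2.
#'
#' @param cfg a [sim_config()].
#' @param under_h1 logical: generate the skeleton from the target (`TRUE`)
#'   or from the unrelated population (`FALSE`).
#' @param seed optional seed override.
#' @return object of class `case_bundle`: list with `pedigree`, `skeleton_mt`,
#'   `skeleton_y`, `relative_mt`, `relative_y`, `database` (list from
#'   [sample_database()]), `params` (mu, m_mt, r, m_y, priors), and `truth`
#'   (`under_h1`, transmission truth record, skeleton haplotype's true
#'   population frequency, seed).
#' @export
make_case <- function(cfg, under_h1 = TRUE, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- case_pedigree(cfg$case_mt_meioses, cfg$case_y_links)
  spectrum <- population_spectrum(cfg, seed = seed)
  trans <- transmit_markers(ped, cfg, spectrum = spectrum, seed = seed)
  dbs <- sample_database(cfg, spectrum = spectrum, seed = seed)
  target <- attr(ped, "target")
  if (under_h1) {
    skeleton_mt <- trans$mt[[target]]
    skeleton_y <- trans$y[[target]]
    skel_index <- trans$truth$founder_mt_index[["ANCESTRESS"]]
  } else {
    skel_index <- with_seed(seed + 3L,
      sample.int(length(spectrum$freqs), 1L, prob = spectrum$freqs))
    skeleton_mt <- spectrum$mt[[skel_index]]
    skeleton_y <- with_seed(seed + 4L,
      spectrum$y[[sample.int(length(spectrum$freqs), 1L,
                             prob = spectrum$freqs)]])
  }
  skeleton_y$id <- "SKELETON"
  structure(list(
    pedigree = ped,
    skeleton_mt = skeleton_mt, skeleton_y = skeleton_y,
    relative_mt = trans$mt[[attr(ped, "mat_relative")]],
    relative_y = trans$y[[attr(ped, "pat_relative")]],
    database = dbs,
    params = list(mu = cfg$mt_mu, m_mt = cfg$case_mt_meioses,
                  r = cfg$fp_rate, m_y = cfg$case_y_links,
                  priors = 0.5),
    truth = list(under_h1 = under_h1,
                 transmission = trans$truth,
                 skeleton_mt_true_freq =
                   spectrum$freqs[[skel_index]] %||% NA_real_,
                 seed = as.integer(seed))),
    class = "case_bundle")
}

#' @export
print.case_bundle <- function(x, ...) {
  cat(sprintf("<case_bundle> generated under %s (seed %d)\n",
              if (x$truth$under_h1) "H1" else "H2", x$truth$seed))
  cat(sprintf("  matriline: %d meioses; patriline: %d links; database n = %d\n",
              x$params$m_mt, x$params$m_y, length(x$database$db)))
  invisible(x)
}

#' Write / read a case bundle directory
#'
#' All files are the package's own plain-text formats: `pedigree.tsv` (PED
#' dialect), `database.tsv` and `profiles_mt.tsv` (haplotype TSV),
#' `profiles_y.tsv` (wide Y-STR table), `case.json` (parameters) and
#' `truth.json` (ground-truth record).  Re-running with the same
#' configuration and seed reproduces the files byte-identically.
#'
#' @param bundle a [make_case()] bundle.
#' @param dir output directory (created if needed).
#' @return `write_case_bundle()` returns `dir` invisibly;
#'   `read_case_bundle()` returns a `case_bundle`.
#' @export
write_case_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "case_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(bundle$pedigree, file.path(dir, "pedigree.tsv"))
  write_mt_db(bundle$database$db, file.path(dir, "database.tsv"))
  write_mt_db(mt_db(c("SKELETON", "MAT_RELATIVE"),
                    list(bundle$skeleton_mt, bundle$relative_mt)),
              file.path(dir, "profiles_mt.tsv"))
  write_ystr_table(list(bundle$skeleton_y, bundle$relative_y),
                   file.path(dir, "profiles_y.tsv"))
  jsonlite::write_json(
    c(bundle$params,
      list(mat_relative = attr(bundle$pedigree, "mat_relative"),
           pat_relative = attr(bundle$pedigree, "pat_relative"),
           target = attr(bundle$pedigree, "target"))),
    file.path(dir, "case.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(under_h1 = bundle$truth$under_h1,
         skeleton_mt_true_freq = bundle$truth$skeleton_mt_true_freq,
         seed = bundle$truth$seed,
         fp_links = bundle$truth$transmission$fp_links,
         mt_mutations = bundle$truth$transmission$mt_mutations,
         str_mutations = bundle$truth$transmission$str_mutations),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_case_bundle
#' @export
read_case_bundle <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.tsv"))
  params <- jsonlite::read_json(file.path(dir, "case.json"),
                                simplifyVector = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  attr(ped, "target") <- params$target
  attr(ped, "mat_relative") <- params$mat_relative
  attr(ped, "pat_relative") <- params$pat_relative
  profs <- read_mt_db(file.path(dir, "profiles_mt.tsv"))
  ys <- read_ystr_table(file.path(dir, "profiles_y.tsv"))
  names(ys) <- vapply(ys, `[[`, "", "id")
  dbs <- list(db = read_mt_db(file.path(dir, "database.tsv")))
  structure(list(
    pedigree = ped,
    skeleton_mt = profs$haplotypes[[match("SKELETON", profs$ids)]],
    skeleton_y = ys[["SKELETON"]],
    relative_mt = profs$haplotypes[[match("MAT_RELATIVE", profs$ids)]],
    relative_y = ys[[params$pat_relative]],
    database = dbs,
    params = params[c("mu", "m_mt", "r", "m_y", "priors")],
    truth = list(under_h1 = isTRUE(truth$under_h1),
                 transmission = truth[c("fp_links", "mt_mutations",
                                        "str_mutations")],
                 skeleton_mt_true_freq = truth$skeleton_mt_true_freq,
                 seed = truth$seed)),
    class = "case_bundle")
}
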