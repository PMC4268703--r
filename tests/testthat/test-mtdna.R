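CR_RANGES <- mt_ranges("16093-16320 73-188")

test_that("range declarations parse and validate", {
  expect_equal(CR_RANGES$start, c(73L, 16093L))
  expect_equal(CR_RANGES$end, c(188L, 16320L))
  expect_kinlr_error(mt_ranges("16093-16320 73"), "kinlr_bad_range")
  expect_kinlr_error(mt_ranges("0-100"), "kinlr_bad_range")
  expect_kinlr_error(mt_ranges("200-100"), "kinlr_bad_range")
  expect_kinlr_error(mt_ranges("16000-17000"), "kinlr_bad_range")
})

test_that("variant profiles parse with range and token validation", {
  h <- parse_variant_profile("", mt_ranges("73-188"))
  expect_length(h$variants, 0L)

  h <- parse_variant_profile("16126C 73G", CR_RANGES)
  expect_identical(h$variants, c("73G", "16126C"))

  expect_identical(parse_variant_profile("16126c", CR_RANGES)$variants, "16126C")

  expect_kinlr_error(parse_variant_profile("16400T", mt_ranges("16093-16320")),
                     "kinlr_out_of_range")
  expect_kinlr_error(parse_variant_profile("16126C 16126T", CR_RANGES),
                     "kinlr_duplicate_position")
  expect_kinlr_error(parse_variant_profile("16126R", CR_RANGES),
                     "kinlr_bad_token")  # ambiguity codes rejected
  expect_kinlr_error(parse_variant_profile("xyz", CR_RANGES), "kinlr_bad_token")

  # indel tokens are accepted as opaque strings
  h <- parse_variant_profile("315.1C 249DEL 73G", mt_ranges("73-400"))
  expect_identical(h$variants, c("73G", "249DEL", "315.1C"))
})

test_that("profiles derived from aligned sequences equal a position-wise diff", {
  ref <- toy_reference()
  ranges <- mt_ranges("101-400 601-900", max_pos = 1000L)

  expect_length(profile_from_fasta(ref, ref, ranges)$variants, 0L)

  s <- ref
  substr(s, 150, 150) <- if (substr(ref, 150, 150) == "A") "C" else "A"
  h <- profile_from_fasta(s, ref, ranges)
  expect_identical(h$variants, sprintf("150%s", substr(s, 150, 150)))

  # 100 random mutations vs brute-force character comparison
  set.seed(77)
  sv <- strsplit(ref, "")[[1]]
  pos <- sample(1000L, 100L)
  for (p in pos) sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1L)
  mutated <- paste(sv, collapse = "")
  h <- profile_from_fasta(mutated, ref, ranges)
  rv <- strsplit(ref, "")[[1]]
  in_rng <- function(p) any(p >= ranges$start & p <= ranges$end)
  brute <- sprintf("%d%s", which(sv != rv), sv[sv != rv])
  brute <- brute[vapply(which(sv != rv), in_rng, logical(1))]
  expect_setequal(h$variants, brute)

  expect_kinlr_error(profile_from_fasta("ACGT", ref, ranges),
                     "kinlr_length_mismatch")
  bad <- ref; substr(bad, 5, 5) <- "R"
  expect_kinlr_error(profile_from_fasta(bad, ref, ranges), "kinlr_bad_base")

  # N positions are never called
  nn <- ref; substr(nn, 150, 150) <- "N"
  expect_length(profile_from_fasta(nn, ref, ranges)$variants, 0L)
})

test_that("haplotype differences are symmetric set differences over shared ranges", {
  h1 <- parse_variant_profile("16126C 73G", CR_RANGES)
  h2 <- parse_variant_profile("16126C 73G", CR_RANGES)
  expect_length(mt_diff(h1, h2), 0L)

  h3 <- parse_variant_profile("16126C 73G 146C", CR_RANGES)
  expect_identical(mt_diff(h1, h3), "146C")

  # single-site difference pattern: one token, everything else shared
  a <- parse_variant_profile("8994A 73G", mt_ranges("73-188 8900-9000"))
  b <- parse_variant_profile("73G", mt_ranges("73-188 8900-9000"))
  expect_identical(mt_diff(a, b), "8994A")

  # comparison restricted to shared ranges: 16126C is outside h4's declaration
  h4 <- parse_variant_profile("73G", mt_ranges("73-188"))
  expect_length(mt_diff(h1, h4), 0L)

  disjoint <- parse_variant_profile("", mt_ranges("300-400"))
  expect_kinlr_error(mt_diff(h1, disjoint), "kinlr_no_comparable_positions")

  # random pairs: symmetry and equality with a brute-force symmetric difference
  set.seed(19)
  for (i in 1:20) {
    p1 <- random_profile(CR_RANGES, n_var = sample(0:5, 1))
    p2 <- random_profile(CR_RANGES, n_var = sample(0:5, 1))
    d12 <- mt_diff(p1, p2)
    expect_identical(sort(d12), sort(mt_diff(p2, p1)))
    brute <- union(setdiff(p1$variants, p2$variants),
                   setdiff(p2$variants, p1$variants))
    expect_setequal(d12, brute)
    expect_length(mt_diff(p1, p1), 0L)
  }
})

test_that("database match counting equals a brute-force scan and reports skips", {
  q <- parse_variant_profile("16126C 73G", CR_RANGES)
  empty <- mt_db()
  expect_equal(as.integer(count_db_matches(empty, q)), 0L)

  five <- mt_db(sprintf("r%d", 1:5), replicate(5, q, simplify = FALSE))
  expect_equal(as.integer(count_db_matches(five, q)), 5L)

  # 1,000 simulated records with a planted number of matches
  set.seed(23)
  n <- 1000L
  planted <- 17L
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      r <- random_profile(CR_RANGES, n_var = sample(0:4, 1))
      if (!identical(r$variants, q$variants)) break
    }
    recs[[i]] <- r
  }
  recs[sample(n, planted)] <- replicate(planted, q, simplify = FALSE)
  db <- mt_db(sprintf("s%04d", seq_len(n)), recs)
  k <- count_db_matches(db, q)
  expect_equal(as.integer(k), planted)
  brute <- sum(vapply(recs, function(r) identical(r$variants, q$variants),
                      logical(1)))
  expect_equal(as.integer(k), brute)
  expect_equal(attr(k, "skipped"), 0L)

  # a record declaring narrower ranges cannot be compared and is skipped
  narrow <- parse_variant_profile("73G", mt_ranges("73-188"))
  db2 <- mt_db(c("a", "b"), list(narrow, q))
  k2 <- count_db_matches(db2, q)
  expect_equal(as.integer(k2), 1L)
  expect_equal(attr(k2, "skipped"), 1L)
})

test_that("conservative match probability reproduces the pseudocount convention", {
  expect_equal(match_probability(0, 1831), 2 / 1832)
  expect_equal(match_probability(0, 26127), 2 / 26128)
  expect_equal(match_probability(5, 10, add_relative = FALSE, pseudocount = 0), 0.5)
  expect_kinlr_error(match_probability(11, 10), "kinlr_bad_argument")

  # conservatism: with defaults, always strictly above the plain frequency
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:5000, 1)
    k <- sample(0:n, 1)
    expect_gt(match_probability(k, n), k / n)
  }
})

test_that("no-mutation probability follows (1 - mu)^m with its limit behaviour", {
  expect_equal(no_mutation_prob(0.3, 0), 1)
  mu <- 10 / 327
  # independent oracle: repeated multiplication rather than exponentiation
  expect_equal(no_mutation_prob(mu, 19), prod(rep(1 - mu, 19)))
  expect_equal(round(no_mutation_prob(mu, 19), 4), 0.5543)
  expect_equal(round(no_mutation_prob(mu, 21), 4), 0.5209)

  # strictly decreasing in m for mu > 0
  vals <- vapply(0:30, function(m) no_mutation_prob(mu, m), numeric(1))
  expect_true(all(diff(vals) < 0))

  # first-order accuracy for small m*mu
  set.seed(8)
  for (i in 1:20) {
    mu2 <- stats::runif(1, 0, 0.01)
    m <- sample(1:10, 1)
    expect_lte(abs(no_mutation_prob(mu2, m) - (1 - m * mu2)), (m * mu2)^2)
  }
  expect_kinlr_error(no_mutation_prob(1, 3), "kinlr_bad_argument")
  expect_kinlr_error(no_mutation_prob(0.1, 2.5), "kinlr_bad_argument")
})

test_that("mtDNA likelihood ratio divides no-mutation probability by match probability", {
  expect_equal(mtdna_lr(p_match = 1, mu = 0, m = 19), 1)  # neutral
  expect_equal(mtdna_lr(p_match = 0.001, p_no_mutation = 0.5), 500)
  # with the reported no-mutation constant and the very conservative match
  # probability, the LR lands near the published value
  lr <- mtdna_lr(p_match = 2 / 1832, p_no_mutation = 0.52)
  expect_equal(lr, 0.52 * 1832 / 2)
  expect_equal(round(lr, 1), 476.3)
  expect_kinlr_error(mtdna_lr(p_match = 0, p_no_mutation = 0.5),
                     "kinlr_bad_argument")
})

test_that("a second relative's conditional observation cancels in the LR", {
  expect_identical(second_relative_lr(), 1)
  items <- list(evidence_item("a", lr = 3.5),
                evidence_item("second_rel", lr = second_relative_lr()),
                evidence_item("second_rel2", lr = second_relative_lr()))
  expect_equal(combine_evidence(items)$lr, 3.5)
})

test_that("haplotype database TSV round-trips through its reader and writer", {
  set.seed(91)
  db <- mt_db(sprintf("h%d", 1:8),
              replicate(8, random_profile(CR_RANGES, n_var = sample(0:3, 1)),
                        simplify = FALSE))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_mt_db(db, f1)
  db2 <- read_mt_db(f1)
  write_mt_db(db2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(length(db2), 8L)
})

test_that("end-to-end transmission matches the closed-form no-mutation probability", {
  # moderate-scale check (the full-scale one runs with the acceptance suite):
  # fraction of perfect 10-meiosis transmissions ~ (1 - mu)^10
  ped <- chain_pedigree(11L, "mat")
  mu <- 0.02
  cfg <- sim_config(seed = 1L, fp_rate = 0, mt_mu = mu, str_rate = 0,
                    db_size = 0L)
  spectrum <- population_spectrum(cfg)
  n_rep <- 2000L
  ok <- vapply(seq_len(n_rep), function(i) {
    tr <- transmit_markers(ped, cfg, spectrum = spectrum, seed = i)
    length(mt_diff(tr$mt[["C1"]], tr$mt[["C11"]])) == 0L
  }, logical(1))
  expected <- (1 - mu)^10
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_lt(abs(mean(ok) - expected), 3 * se)
})
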