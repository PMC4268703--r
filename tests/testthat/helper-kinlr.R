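# Shared fixture builders.  Everything is generated in code; tests never read
# files that are not produced during the run.

# Minimal child/father/mother triad.
triad_df <- function() {
  data.frame(id = c("child", "dad", "mum"),
             father_id = c("dad", "0", "0"),
             mother_id = c("mum", "0", "0"),
             sex = c("male", "male", "female"))
}

# A random but structurally valid pedigree table: individuals are created in
# order and may draw parents from earlier, correctly sexed individuals.
random_pedigree_df <- function(n, seed) {
  set.seed(seed)
  id <- sprintf("IND%03d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  father <- mother <- rep("0", n)
  for (i in seq_len(n)) {
    males <- id[seq_len(i - 1L)][sex[seq_len(i - 1L)] == "male"]
    females <- id[seq_len(i - 1L)][sex[seq_len(i - 1L)] == "female"]
    if (length(males) > 0L && stats::runif(1) < 0.6)
      father[i] <- sample(males, 1L)
    if (length(females) > 0L && stats::runif(1) < 0.6)
      mother[i] <- sample(females, 1L)
  }
  data.frame(id = id, father_id = father, mother_id = mother, sex = sex)
}

# Uniparental chain of `n` individuals (n - 1 links), e.g. for transmission
# replicates.  lineage = "pat" (all-male father chain) or "mat".
chain_pedigree <- function(n, lineage = c("pat", "mat")) {
  lineage <- match.arg(lineage)
  ids <- sprintf("C%d", seq_len(n))
  parent <- c("0", ids[-n])
  df <- if (lineage == "pat")
    data.frame(id = ids, father_id = parent, mother_id = "0", sex = "male")
  else
    data.frame(id = ids, father_id = "0", mother_id = parent, sex = "female")
  suppressWarnings(pedigree(df))
}

# Toy circular "mini-rCRS": a fixed-seed random 1,000-bp reference.
toy_reference <- function(len = 1000L, seed = 42L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random EMPOP-style profile over given ranges (substitutions only).
random_profile <- function(ranges, n_var = 3L) {
  positions <- unlist(lapply(seq_len(nrow(ranges)), function(i)
    ranges$start[i]:ranges$end[i]))
  pos <- sample(positions, min(n_var, length(positions)))
  mt_haplotype(sprintf("%d%s", pos,
                       sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)),
               ranges, max_pos = max(ranges$end))
}

# Toy 3-locus Y panel and haplotype for compact comparison tests.
toy_panel <- function() ystr_panel(c("L1", "L2", "DYS385"), multi_copy = "DYS385")

toy_yhap <- function(l1 = 12, l2 = 15, dys385 = c(11, 14), id = NA,
                     haplogroup = NA) {
  ystr_haplotype(list(L1 = l1, L2 = l2, DYS385 = dys385), panel = toy_panel(),
                 id = id, haplogroup = haplogroup)
}

expect_kinlr_error <- function(expr, class) {
  expect_error(expr, class = class)
}
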