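test_that("tryptic digestion honors proline suppression and missed cleavages", {
  r0 <- cleavage_rule("[RK]|{P}", 0)
  expect_setequal(digest("AKPRGK", r0)$sequence, c("AKPR", "GK"))
  r1 <- cleavage_rule("[RK]|{P}", 1)
  expect_setequal(digest("AKPRGK", r1)$sequence, c("AKPR", "GK", "AKPRGK"))
  # no cleavable residue: the protein itself
  expect_equal(digest("AGSTV", r0)$sequence, "AGSTV")
  expect_equal(nrow(digest("", r0)), 0L)
})

test_that("digestion matches exhaustive site enumeration on random proteins", {
  set.seed(7)
  for (trial in 1:20) {
    prot <- paste(sample(names(msdbsearch:::AA_MASS), 60, replace = TRUE),
                  collapse = "")
    mm <- sample(0:2, 1)
    rule <- cleavage_rule("[RK]|{P}", mm)
    got <- digest(prot, rule)
    # oracle: enumerate cut positions directly, then all j-missed substrings
    res <- strsplit(prot, "")[[1]]
    sites <- which(res[-60] %in% c("R", "K") & res[-1] != "P")
    bounds <- c(0, sites, 60)
    exp_seq <- character(0); exp_miss <- integer(0)
    for (a in seq_along(bounds)[-length(bounds)]) {
      for (b in (a + 1):min(length(bounds), a + 1 + mm)) {
        exp_seq <- c(exp_seq, substring(prot, bounds[a] + 1, bounds[b]))
        exp_miss <- c(exp_miss, b - a - 1L)
      }
    }
    expect_equal(got$sequence, exp_seq)
    expect_equal(got$missed, exp_miss)
    # count property: c non-suppressed sites -> c+1 zero-missed peptides
    expect_equal(sum(got$missed == 0), length(sites) + 1L)
  }
})

test_that("modified-form enumeration emits every allowed combination", {
  forms <- enumerate_modified_forms("ACM", mod_scheme(max_variable = 2))
  expect_length(forms, 10L)  # M yes/no x (no N-term + 4 N-term choices)
  expect_length(unique(forms), 10L)
  expect_length(enumerate_modified_forms("AAA", static_scheme()), 1L)
  deam <- mod_scheme(variable = c(N = 0.984016, Q = 0.984016),
                     nterm = numeric(0), max_variable = 1)
  expect_setequal(enumerate_modified_forms("NQ", deam),
                  c("NQ", "N[+0.984016]Q", "NQ[+0.984016]"))
  # static mods appear in every form
  expect_true(all(grepl("C\\[\\+57", enumerate_modified_forms("ACK"))))
})

test_that("modified-form count matches the truncated closed form", {
  set.seed(11)
  sch <- mod_scheme()  # M, N, Q variable; 4 N-term; max 3
  for (trial in 1:15) {
    pep <- paste(sample(names(msdbsearch:::AA_MASS), sample(3:8, 1),
                        replace = TRUE), collapse = "")
    v <- sum(strsplit(pep, "")[[1]] %in% names(sch$variable))
    nt <- length(sch$nterm)
    expected <- 0
    for (k in 0:min(v, sch$max_variable)) {
      expected <- expected + choose(v, k) *
        (1 + if (k < sch$max_variable) nt else 0)
    }
    expect_length(enumerate_modified_forms(pep, sch), expected)
  }
})

test_that("peptide masses follow the residue table plus deltas plus water", {
  expect_equal(peptide_mass("G"), 75.032024, tolerance = 1e-6)
  expect_equal(peptide_mass("C[+57.021460]"), 178.041210, tolerance = 1e-6)
  # additivity: explicit zero deltas change nothing
  expect_equal(peptide_mass("PEPTIDEK"),
               peptide_mass("P[+0.000000]EPTIDEK[+0.000000]"))
  expect_error(peptide_mass("AB"), "unknown residue")
})

test_that("decoys are mass-preserving C-terminus-fixed shuffles", {
  d <- make_decoy("AK", seed = 1)
  expect_true(d$collision)
  expect_equal(d$peptide, "AK")
  # frozen regression: fixed permutation for a fixed seed
  expect_equal(make_decoy("PEPTIDEK", seed = 7)$peptide, "EPTDEPIK")
  expect_equal(make_decoy("PEPTIDEK", seed = 7)$peptide,
               make_decoy("PEPTIDEK", seed = 7)$peptide)
  set.seed(5)
  for (trial in 1:25) {
    pep <- paste(sample(names(msdbsearch:::AA_MASS), sample(4:12, 1),
                        replace = TRUE), collapse = "")
    d <- make_decoy(pep, seed = trial)
    expect_equal(sort(strsplit(d$peptide, "")[[1]]),
                 sort(strsplit(pep, "")[[1]]))
    expect_equal(substring(d$peptide, nchar(pep)), substring(pep, nchar(pep)))
    expect_equal(peptide_mass(d$peptide), peptide_mass(pep),
                 tolerance = 1e-6)
  }
  # modifications travel with their residues
  d <- make_decoy("AM[+15.994915]DEFK", seed = 2)
  expect_equal(peptide_mass(d$peptide), peptide_mass("AM[+15.994915]DEFK"),
               tolerance = 1e-9)
})

test_that("FASTA reading preserves order and uppercases with a warning", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 first protein", "AKPRGK", ">p2", "GGSTR"), f)
  prot <- read_fasta(f)
  expect_equal(prot$id, c("p1", "p2"))
  expect_equal(prot$sequence, c("AKPRGK", "GGSTR"))
  expect_equal(prot$description[1], "p1 first protein")
  writeLines(c(">p1", "akr"), f)
  expect_warning(low <- read_fasta(f), "lowercase")
  expect_equal(low$sequence, "AKR")
  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0L)
})

test_that("precursor windows convert m/z and charge to neutral-mass bounds", {
  w <- precursor_window(501.00728, 2, 20)
  expect_equal(mean(w), 1000, tolerance = 1e-8)
  expect_equal(diff(w) / 2, 0.02, tolerance = 1e-6)
  expect_error(precursor_window(500, 2, 0))
  expect_error(precursor_window(0.5, 1, 20), "non-positive")
})

test_that("candidate index queries agree with a linear scan", {
  prot <- simulate_proteome(10, 120, seed = 42)
  idx <- build_peptide_index(prot, scheme = static_scheme(), decoy_seed = 3)
  masses <- idx$peptides$mass
  set.seed(13)
  for (trial in 1:100) {
    a <- runif(1, min(masses) - 50, max(masses) + 50)
    b <- a + runif(1, 0, 200)
    got <- query_candidates(idx, c(a, b))
    expect_equal(got$peptide,
                 idx$peptides$peptide[masses >= a & masses <= b])
    expect_true(!is.unsorted(got$mass))
  }
  # empty and all-covering intervals
  expect_equal(nrow(query_candidates(idx, c(0, 1))), 0L)
  expect_equal(nrow(query_candidates(idx, range(masses))),
               nrow(idx$peptides))
})

test_that("peptides with ambiguous residues are excluded from the index", {
  prot <- data.frame(id = "p", description = "p",
                     sequence = "AAAAAXAAAKGGGGGGKCCCCCCK")
  idx <- build_peptide_index(prot, scheme = static_scheme(),
                             min_len = 6, max_len = 50)
  expect_false(any(grepl("X", idx$peptides$peptide)))
  expect_gt(idx$n_ambiguous_dropped, 0L)
})
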