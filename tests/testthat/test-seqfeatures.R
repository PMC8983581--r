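# FG-motif valence accounting and sequence mutations.

test_that("motif scans count FG and GLFG correctly on hand-built strings", {
  s <- protein_sequence("x", "FGSFG")
  expect_equal(count_fg(s), 2)
  g <- protein_sequence("x", "GLFGGLFG")
  expect_equal(count_glfg(g), 2)
  expect_equal(count_fg(g), 2)   # each GLFG counted once as FG
  expect_warning(n <- count_fg(protein_sequence("e", "")), "empty")
  expect_equal(n, 0)
})

test_that("counts are case-insensitive and GLFG is always a subset of FG", {
  lower <- protein_sequence("x", "fgsglfgtt")
  expect_equal(count_fg(lower), 2)
  expect_equal(count_glfg(lower), 1)
  set.seed(31)
  for (rep in 1:10) {
    res <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 300,
                        replace = TRUE), collapse = "")
    s <- protein_sequence("r", res)
    expect_gte(count_fg(s), count_glfg(s))
  }
})

test_that("motif scans agree with a brute-force position-by-position oracle", {
  set.seed(99)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:50) {
    res <- paste(sample(aas, 200, replace = TRUE), collapse = "")
    s <- protein_sequence("r", res)
    ch <- strsplit(res, "")[[1]]
    fg_brute <- sum(vapply(seq_len(199), function(i) {
      ch[i] == "F" && ch[i + 1] == "G"
    }, logical(1)))
    glfg_brute <- sum(vapply(seq_len(197), function(i) {
      all(ch[i:(i + 3)] == c("G", "L", "F", "G"))
    }, logical(1)))
    expect_equal(count_fg(s), fg_brute)
    expect_equal(count_glfg(s), glfg_brute)
  }
})

test_that("region-restricted counts respect interval bounds", {
  s <- protein_sequence("x", "FGAAAGLFGAAFG",
                        regions = list(head = c(1, 5), tail = c(6, 13)))
  expect_equal(count_fg(s, "head"), 1)
  expect_equal(count_fg(s, "tail"), 2)
  expect_equal(count_fg(s, c(1, 13)), 3)
  expect_error(count_fg(s, c(0, 5)), "bounds")
  expect_error(count_fg(s, "nope"), "unknown region")
})

test_that("mutations drop exactly the targeted motifs and keep length", {
  s <- generate_construct_sequence(17, 21, 3, 6, seed = 2)
  n0 <- nchar(s$residues)
  spec21 <- mutation_spec_for_motifs(s, "cterm", "FG>AA")
  m21 <- apply_mutations(s, spec21)
  expect_equal(count_fg(m21), 17)
  expect_equal(nchar(m21$residues), n0)
  spec8 <- mutation_spec_for_motifs(s, "cterm", "F>A", n = 8)
  m8 <- apply_mutations(s, spec8)
  expect_equal(count_fg(m8), 30)
  expect_identical(apply_mutations(s, data.frame(position = integer(0),
                                                 kind = character(0)))$residues,
                   s$residues)
})

test_that("valence arithmetic holds for partial FG>AA specs", {
  s <- generate_construct_sequence(10, 14, 2, 5, seed = 7)
  for (k in c(1, 5, 14)) {
    spec <- mutation_spec_for_motifs(s, "cterm", "FG>AA", n = k)
    expect_equal(count_fg(apply_mutations(s, spec)), count_fg(s) - k)
  }
})

test_that("mutation specs are validated against the parent residues", {
  s <- protein_sequence("x", "AFGA")
  expect_error(apply_mutations(s, data.frame(position = 1, kind = "F>A")),
               "expected 'F'")
  expect_error(apply_mutations(s, data.frame(position = 9, kind = "F>A")),
               "out of bounds")
  m <- apply_mutations(s, data.frame(position = 2, kind = "FG>AA"))
  expect_equal(m$residues, "AAAA")
  expect_error(apply_mutations(protein_sequence("y", "AFA"),
                               data.frame(position = 2, kind = "FG>AA")),
               "'G'")
})

test_that("composition fractions cover trivial cases and the window identity", {
  expect_equal(composition_fraction(protein_sequence("a", "NQST"),
                                    c("N", "Q", "S", "T")), 1)
  expect_equal(composition_fraction(protein_sequence("b", "AAAA"),
                                    c("N", "Q", "S", "T")), 0)
  s <- generate_construct_sequence(5, 8, 1, 2, seed = 3)
  w <- 25
  set <- c("N", "Q", "S", "T")
  prof <- composition_fraction(s, set, window = w)
  n <- nchar(s$residues)
  hit <- strsplit(s$residues, "")[[1]] %in% set
  # direct window oracle at every start position
  brute <- vapply(seq_len(n - w + 1), function(i) mean(hit[i:(i + w - 1)]),
                  numeric(1))
  expect_equal(unname(prof), brute, tolerance = 1e-12)
  # total-count identity: window sums count each position once per
  # covering window (edge positions are covered by fewer windows)
  pos_cover <- vapply(seq_len(n), function(i) {
    min(i, n - w + 1) - max(1, i - w + 1) + 1
  }, numeric(1))
  expect_equal(sum(prof * w), sum(pos_cover * hit), tolerance = 1e-9)
  expect_error(composition_fraction(s, "N", window = n + 1), "window")
})

test_that("FASTA round trip preserves sequences", {
  seqs <- list(generate_construct_sequence(3, 4, 1, 1, seed = 1),
               protein_sequence("plain", "MKVLNQSTFG"))
  path <- file.path(withr::local_tempdir(), "constructs.fasta")
  write_fasta_sequences(seqs, path)
  back <- read_fasta_sequences(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$residues, seqs[[1]]$residues)
  expect_equal(back[[2]]$residues, "MKVLNQSTFG")
})
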