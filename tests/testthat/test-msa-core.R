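# Sequence handling, pairwise identity, clustering, the progressive aligner
# and conservation scoring.

test_that("pairwise identity follows the shorter-sequence convention", {
  expect_equal(pairwise_identity("MKTAYIAK", "MKTAYIAK"), 1.0)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  # a perfect prefix: 4 identities over the 4-residue shorter sequence
  expect_equal(pairwise_identity("MKTAYIAK", "MKTA"), 1.0)
  expect_error(pairwise_identity("", "MKTA"), "non-empty")
})

test_that("pairwise identity is symmetric and reflexive on random pairs", {
  wyldomkit:::with_seed(11, {
    for (rep in 1:8) {
      a <- paste(sample(wyldomkit:::AA_ALPHABET, sample(10:40, 1),
                        replace = TRUE), collapse = "")
      b <- paste(sample(wyldomkit:::AA_ALPHABET, sample(10:40, 1),
                        replace = TRUE), collapse = "")
      expect_equal(pairwise_identity(a, a), 1.0)
      expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    }
  })
})

test_that("global alignment agrees with an independent aligner", {
  skip_if_not_installed("Biostrings")
  wyldomkit:::with_seed(23, {
    for (rep in 1:5) {
      a <- paste(sample(wyldomkit:::AA_ALPHABET, 30, replace = TRUE),
                 collapse = "")
      b <- paste(c(sample(strsplit(a, "")[[1]], 25),
                   sample(wyldomkit:::AA_ALPHABET, 5, replace = TRUE)),
                 collapse = "")
      ours <- align_global(a, b)
      ref <- Biostrings::pairwiseAlignment(
        a, b, type = "global",
        substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 1)
      # same penalty scheme: our open -11 charges open+extend on the first
      # gap residue, Biostrings charges opening 10 plus extension 1
      expect_equal(ours$score, Biostrings::score(ref))
    }
  })
})

test_that("greedy clustering groups by representative identity", {
  rec <- seq_set(paste0("s", 1:5), rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 5))
  cs <- greedy_cluster(rec, 0.7)
  expect_length(cs$clusters, 1L)
  expect_length(cs$clusters[[1]], 5L)

  # all-distinct random sequences at threshold 1 -> singletons
  distinct <- wyldomkit:::with_seed(5, {
    seq_set(paste0("d", 1:6), vapply(1:6, function(i) {
      paste(sample(wyldomkit:::AA_ALPHABET, 30, replace = TRUE), collapse = "")
    }, character(1)))
  })
  expect_length(greedy_cluster(distinct, 1.0)$clusters, 6L)
  # threshold near zero -> one cluster
  expect_length(greedy_cluster(distinct, 1e-9)$clusters, 1L)
})

test_that("two synthetic families are recovered exactly at threshold 0.7", {
  lib <- make_domain_library(808L, 2L, c(80L, 80L),
                             names = c("famA", "famB"))
  fam_a <- mutated_copies(lib$famA, 6, 0.04, 61L, indel_rate = 0)
  fam_b <- mutated_copies(lib$famB, 6, 0.04, 62L, indel_rate = 0)
  recs <- rbind(fam_a, fam_b)
  class(recs) <- c("seq_set", "data.frame")

  # brute-force check of the generator's identity structure
  within_ok <- between_ok <- TRUE
  for (i in 1:6) {
    for (j in 1:6) {
      if (i < j) {
        within_ok <- within_ok &&
          pairwise_identity(fam_a$residues[i], fam_a$residues[j]) >= 0.85 &&
          pairwise_identity(fam_b$residues[i], fam_b$residues[j]) >= 0.85
      }
      between_ok <- between_ok &&
        pairwise_identity(fam_a$residues[i], fam_b$residues[j]) <= 0.35
    }
  }
  expect_true(within_ok)
  expect_true(between_ok)

  cs <- greedy_cluster(recs, 0.70)
  expect_length(cs$clusters, 2L)
  members <- lapply(cs$clusters, sort)
  expect_setequal(members, list(sort(fam_a$id), sort(fam_b$id)))
})

test_that("pair concatenation preserves order, ids and lengths", {
  p1 <- list(seq_set("ID1", "MKT")[1, ], seq_set("ID2", "AYI")[1, ])
  out <- concatenate_pairs(list(p1))
  expect_equal(out$id, "ID1|ID2")
  expect_equal(out$residues, "MKTAYI")
  expect_equal(nrow(concatenate_pairs(list())), 0L)

  wyldomkit:::with_seed(31, {
    pairs <- lapply(1:5, function(i) {
      list(seq_set(paste0("a", i),
                   paste(sample(wyldomkit:::AA_ALPHABET, sample(5:30, 1),
                                replace = TRUE), collapse = ""))[1, ],
           seq_set(paste0("b", i),
                   paste(sample(wyldomkit:::AA_ALPHABET, sample(5:30, 1),
                                replace = TRUE), collapse = ""))[1, ])
    })
    out <- concatenate_pairs(pairs)
    for (i in 1:5) {
      expect_equal(nchar(out$residues[i]),
                   nchar(pairs[[i]][[1]]$residues) +
                     nchar(pairs[[i]][[2]]$residues))
    }
  })
  expect_error(concatenate_pairs(list(p1, p1)), "duplicate")
})

test_that("progressive alignment round-trips every input row", {
  one <- progressive_align(seq_set("x", "MKTAYIAK"))
  expect_equal(one$seqs, "MKTAYIAK")

  two <- progressive_align(seq_set(c("x", "y"), rep("MKTAYIAK", 2)))
  expect_equal(two$seqs, rep("MKTAYIAK", 2))

  lib <- wyl_library()
  recs <- mutated_copies(lib$WYL, 8, 0.12, 77L)
  aln <- progressive_align(recs)
  expect_length(aln$ids, 8L)
  for (k in seq_len(8)) {
    expect_equal(ungap_row(aln, recs$id[k]), recs$residues[k])
  }
})

test_that("a planted insertion is gapped out of the other rows", {
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEV"
  ins <- paste0(substr(base, 1, 15), "WWFYP", substr(base, 16, nchar(base)))
  aln <- progressive_align(seq_set(c("a", "b", "c"), c(base, ins, base)))
  expect_equal(n_columns(aln), nchar(ins))
  # the inserted block aligns against gaps in both unmodified rows
  expect_equal(substr(aln$seqs[match("a", aln$ids)], 16, 20), "-----")
  expect_equal(substr(aln$seqs[match("c", aln$ids)], 16, 20), "-----")
  expect_false(grepl("-", aln$seqs[match("b", aln$ids)], fixed = TRUE))
})

test_that("trimming respects the window, drops empty rows, errors on range", {
  aln <- msa(c("a", "b"), c("MK-TA", "M-KTA"))
  expect_equal(trim_alignment(aln, 1, n_columns(aln))$seqs, aln$seqs)

  two <- msa(c("a", "b"), c("MA", "-A"))
  tr <- trim_alignment(two, 1, 1)
  expect_equal(tr$ids, "a")

  wyldomkit:::with_seed(13, {
    recs <- mutated_copies(wyl_library()$HTH, 5, 0.1, 99L)
    big <- progressive_align(recs)
    s <- sample(n_columns(big) - 5, 1)
    e <- s + 5L
    expect_lte(n_columns(trim_alignment(big, s, e)), e - s + 1L)
  })
  expect_error(trim_alignment(aln, 0, 3), "out of range")
  expect_error(trim_alignment(aln, 3, 99), "out of range")
})

test_that("trim then ungap equals substring extraction on gap-free rows", {
  aln <- msa(c("a", "b"), c("MKTAYIAK", "MKWAYIAC"))
  tr <- trim_alignment(aln, 3, 6)
  expect_equal(ungap_row(tr, "a"), substr("MKTAYIAK", 3, 6))
  expect_equal(ungap_row(tr, "b"), substr("MKWAYIAC", 3, 6))
})

test_that("entropy conservation matches hand-computed values", {
  ident <- msa(paste0("r", 1:4), rep("AAAA", 4))
  expect_equal(as.numeric(conservation_scores(ident)), rep(1, 4))

  # all twenty residues equally frequent -> zero conservation
  uniform <- msa(paste0("r", 1:20),
                 vapply(wyldomkit:::AA_ALPHABET, function(a) {
                   paste(rep(a, 3), collapse = "")
                 }, character(1)))
  expect_equal(as.numeric(conservation_scores(uniform)), rep(0, 3))

  # column AAAB: H = -(0.75 ln 0.75 + 0.25 ln 0.25)
  aln <- msa(paste0("r", 1:4), c("AM", "AM", "AM", "DM"))
  H <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(conservation_scores(aln)[1], 1 - H / log(20))

  # a column of only unknown residues has no defined score
  xcol <- msa(c("a", "b"), c("XM", "XM"))
  expect_true(is.na(conservation_scores(xcol)[1]))
  # gap-majority columns are flagged
  gappy <- msa(paste0("r", 1:4), c("AM", "-M", "-M", "-M"))
  expect_true(attr(conservation_scores(gappy), "low_confidence")[1])
  expect_error(conservation_scores(msa("a", "MK")), ">= 2 rows")
})

test_that("conservation is row-permutation invariant and monotone", {
  seqs <- c("AMKT", "DMKT", "AMCT", "AWKT")
  a <- conservation_scores(msa(paste0("r", 1:4), seqs))
  b <- conservation_scores(msa(paste0("r", 1:4), seqs[c(3, 1, 4, 2)]))
  expect_equal(unname(a), unname(b))

  # replacing the minority residue by the majority never lowers the score
  before <- conservation_scores(msa(paste0("r", 1:4), c("AM", "AM", "AM", "DM")))
  after <- conservation_scores(msa(paste0("r", 1:4), c("AM", "AM", "AM", "AM")))
  expect_gte(after[1], before[1])

  sp <- conservation_scores(msa(paste0("r", 1:4), c("AM", "AM", "AM", "DM")),
                            method = "sum_of_pairs")
  expect_length(sp, 2L)
})

test_that("FASTA and aligned-FASTA I/O round-trip", {
  recs <- seq_set(c("a", "b"), c("MKTAYIAK", "MKWAX"))
  tf <- tempfile(fileext = ".fasta")
  write_fasta(recs, tf)
  back <- read_fasta(tf)
  expect_equal(back$id, recs$id)
  expect_equal(back$residues, recs$residues)

  aln <- msa(c("a", "b"), c("MK-TA", "M-KTA"))
  ta <- tempfile(fileext = ".fasta")
  write_msa(aln, ta)
  expect_equal(read_msa(ta)$seqs, aln$seqs)

  cs <- greedy_cluster(recs, 1e-6)
  tc <- tempfile(fileext = ".tsv")
  write_clusters(cs, tc)
  tab <- read.delim(tc)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("cluster_id", "representative", "member_id", "identity"))
})
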