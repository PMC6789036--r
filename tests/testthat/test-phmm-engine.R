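# Profile-HMM engine: model construction, Viterbi/Forward against the
# path-enumeration oracle, envelopes, calibration, E-values, search and scan.

test_that("match-column assignment follows the gap-fraction rule", {
  gapfree <- msa(paste0("r", 1:3), c("MKTA", "MKWA", "MCTA"))
  expect_true(all(assign_match_columns(gapfree)))

  # first column 3/4 gaps -> insert column at the default threshold
  aln <- msa(paste0("r", 1:4), c("MKTA", "-KWA", "-CTA", "-KTA"))
  mask <- assign_match_columns(aln, 0.5)
  expect_false(mask[1])
  expect_true(all(mask[-1]))
  expect_length(mask, n_columns(aln))
  expect_equal(build_profile(aln)$M, sum(mask))

  sparse <- msa(paste0("r", 1:4), c("MKT-", "MK-A", "M-TA", "-KTA"))
  expect_error(assign_match_columns(sparse, 0.2), "curate")
})

test_that("profiles are valid probability models on random alignments", {
  wyldomkit:::with_seed(17, {
    for (rep in 1:20) {
      n <- sample(2:6, 1)
      len <- sample(5:25, 1)
      rows <- vapply(seq_len(n), function(r) {
        chars <- sample(c(wyldomkit:::AA_ALPHABET, "-"), len,
                        replace = TRUE, prob = c(rep(0.9 / 20, 20), 0.1))
        paste(chars, collapse = "")
      }, character(1))
      rows[1] <- gsub("-", "A", rows[1])  # keep every column occupied once
      aln <- msa(paste0("r", seq_len(n)), rows)
      m <- build_profile(aln, pseudocount_weight = runif(1, 0.1, 3))
      expect_silent(validate_profile(m))
      expect_equal(rowSums(m$match_emissions), rep(1, m$M))
      expect_equal(m$M, sum(assign_match_columns(aln)))
    }
  })
})

test_that("emissions approach indicators as pseudocounts vanish", {
  aln <- msa("only", "MKTAY")
  m <- build_profile(aln, pseudocount_weight = 1e-9)
  idx <- wyldomkit:::encode_residues("MKTAY")
  for (k in 1:5) {
    expect_gt(m$match_emissions[k, idx[k]], 1 - 1e-6)
  }
})

test_that("Viterbi and Forward match the enumeration oracle on tiny models", {
  # literal path enumeration first, then the memoized oracle is used for the
  # larger sizes after being validated against it
  for (M in 1:3) {
    model <- random_tiny_model(M, 100 + M)
    for (L in c(2, 4, 5)) {
      s <- random_tiny_seq(L, 300 + 10 * M + L)
      for (mh in c(TRUE, FALSE)) {
        pure <- brute_force_scores(model, s, mh, memoize = FALSE)
        memo <- brute_force_scores(model, s, mh, memoize = TRUE)
        expect_equal(pure$viterbi, memo$viterbi, tolerance = 0)
        expect_equal(pure$forward, memo$forward, tolerance = 0)
        expect_lt(abs(viterbi(model, s, multihit = mh)$bit_score -
                        pure$viterbi), 1e-9)
        expect_lt(abs(forward_score(model, s, multihit = mh) -
                        pure$forward), 1e-9)
      }
    }
  }
})

test_that("score ordering and invariances hold", {
  aln <- progressive_align(seq_set(paste0("r", 1:3),
                                   c("ACDACDACD", "ACDACDACD", "ACDACGACD")))
  m <- build_profile(aln, name = "acd")
  expect_gt(viterbi(m, "ACDACDACD")$bit_score,
            viterbi(m, "WWWWWWWWW")$bit_score)

  # the score ignores id and taxon metadata
  r1 <- seq_set("some_id", "ACDACDACD", taxon_id = "sp1")
  r2 <- seq_set("other", "ACDACDACD", taxon_id = "")
  expect_equal(viterbi(m, r1)$bit_score, viterbi(m, r2)$bit_score)

  # forward >= viterbi everywhere
  wyldomkit:::with_seed(71, {
    for (rep in 1:10) {
      s <- paste(sample(wyldomkit:::AA_ALPHABET, sample(5:30, 1),
                        replace = TRUE), collapse = "")
      expect_gte(forward_score(m, s), viterbi(m, s)$bit_score)
    }
  })
})

test_that("doubling a domain-bearing sequence does not lose forward score", {
  models <- tiny_model_library()
  for (model in models) {
    cons <- consensus_sequence(model)
    one <- paste0("MKTA", cons, "QRQS")
    expect_gte(forward_score(model, paste0(one, one)) + 1e-6,
               forward_score(model, one))
  }
})

test_that("domain extraction nests envelopes and recovers planted copies", {
  model <- tiny_model_library()[[1]]
  cons <- consensus_sequence(model)
  linker <- wyldomkit:::with_seed(41, wyldomkit:::random_residues(50L))
  pre <- wyldomkit:::with_seed(42, wyldomkit:::random_residues(20L))
  post <- wyldomkit:::with_seed(43, wyldomkit:::random_residues(20L))
  seqres <- paste0(pre, cons, linker, cons, post)
  hits <- find_domains(model, seqres)
  expect_equal(nrow(hits), 2L)
  true_starts <- c(nchar(pre) + 1L, nchar(pre) + nchar(cons) + nchar(linker) + 1L)
  true_ends <- true_starts + nchar(cons) - 1L
  expect_true(all(abs(hits$env_from - true_starts) <= 5))
  expect_true(all(abs(hits$env_to - true_ends) <= 5))
  expect_true(all(hits$env_from <= hits$ali_from))
  expect_true(all(hits$ali_from <= hits$ali_to))
  expect_true(all(hits$ali_to <= hits$env_to))
  expect_true(all(hits$hmm_from >= 1 & hits$hmm_to <= model$M))
  expect_true(all(diff(hits$env_from) > 0))
  # cores do not overlap
  expect_true(all(hits$ali_from[-1] > hits$ali_to[-nrow(hits)]))
})

test_that("calibration is reproducible and the Gumbel fit is honest", {
  model <- tiny_model_library()[[2]]
  m1 <- calibrate(model, n_random = 150, length = 120, seed = 99)
  m2 <- calibrate(model, n_random = 150, length = 120, seed = 99)
  expect_identical(m1$calibration, m2$calibration)
  expect_error(calibrate(model, n_random = 50, seed = 1), ">= 100")

  # held-out exceedance at the 90th percentile within binomial error
  mu <- m1$calibration[1]; lambda <- m1$calibration[2]
  scores <- wyldomkit:::with_seed(1234, {
    vapply(1:400, function(i) {
      codes <- sample.int(20L, 120L, replace = TRUE, prob = model$background)
      wyldomkit:::viterbi_score(model, as.integer(codes))
    }, numeric(1))
  })
  x90 <- quantile(scores, 0.9, names = FALSE)
  p_fit <- 1 - exp(-exp(-lambda * (x90 - mu)))
  p_emp <- mean(scores > x90)
  se <- sqrt(p_emp * (1 - p_emp) / length(scores))
  expect_lt(abs(p_fit - p_emp), 4 * se + 0.01)
})

test_that("E-values follow the closed form and its monotonicities", {
  model <- tiny_model_library()[[1]]
  model <- calibrate(model, seed = 7)
  mu <- model$calibration[1]
  expect_equal(evalue(mu, model, db_size = 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(evalue(mu + 2, model, db_size = 500),
               500 * evalue(mu + 2, model, db_size = 1))
  expect_lt(evalue(mu + 10, model), evalue(mu, model))

  # the model's own consensus is far in the tail
  cons_bits <- viterbi(model, consensus_sequence(model))$bit_score
  expect_lt(evalue(cons_bits, model, db_size = 10000), 1e-6)

  uncal <- random_tiny_model(3, 5)
  expect_error(evalue(10, uncal, 1), "not calibrated")
})

test_that("threshold containers validate and carry the survey defaults", {
  th <- search_thresholds()
  expect_equal(unlist(th[c("report_E", "report_domE", "include_E",
                           "include_domE")]),
               c(report_E = 1, report_domE = 1, include_E = 0.01,
                 include_domE = 0.03))
  ts <- scan_thresholds()
  expect_equal(unlist(ts[c("report_E", "report_domE", "include_E",
                           "include_domE")]),
               c(report_E = 0.1, report_domE = 0.1, include_E = 0.01,
                 include_domE = 0.03))
  expect_error(search_thresholds(report_E = 0.005, include_E = 0.01),
               "inclusion")
})

test_that("search separates planted from background sequences", {
  model <- calibrate(tiny_model_library()[[1]], seed = 11)
  empty <- hmm_search(model, seq_set(character(), character()))
  expect_equal(nrow(empty$sequences), 0L)

  db <- wyldomkit:::with_seed(50, {
    planted <- vapply(1:100, function(i) {
      pre <- wyldomkit:::random_residues(sample(10:60, 1))
      post <- wyldomkit:::random_residues(sample(10:60, 1))
      paste0(pre, consensus_sequence(model), post)
    }, character(1))
    background <- vapply(1:100, function(i) {
      wyldomkit:::random_residues(sample(80:200, 1))
    }, character(1))
    seq_set(c(paste0("pl", 1:100), paste0("bg", 1:100)),
            c(planted, background))
  })
  res <- hmm_search(model, db)
  inc <- res$sequences$sequence_id[res$sequences$included]
  expect_setequal(inc, paste0("pl", 1:100))
  # ordering is by E-value then id
  expect_true(!is.unsorted(res$sequences$evalue))
})

test_that("scan only reports domains from matching models, in N-C order", {
  models <- lapply(seq_along(tiny_model_library()), function(i) {
    calibrate(tiny_model_library()[[i]], seed = 20 + i)
  })
  # protein built from models 1 and 2, scanned against all three
  protein <- wyldomkit:::with_seed(60, {
    paste0(wyldomkit:::random_residues(25),
           consensus_sequence(models[[1]]),
           wyldomkit:::random_residues(30),
           consensus_sequence(models[[2]]),
           wyldomkit:::random_residues(25))
  })
  hits <- hmm_scan(models, protein)
  inc <- hits[hits$included, ]
  expect_equal(inc$model, c(models[[1]]$name, models[[2]]$name))
  expect_true(all(diff(inc$env_from) > 0))

  # a library lacking the planted domain finds nothing to include
  noise <- wyldomkit:::with_seed(61, {
    paste0(wyldomkit:::random_residues(30),
           consensus_sequence(models[[3]]),
           wyldomkit:::random_residues(30))
  })
  other <- hmm_scan(models[1:2], noise)
  expect_equal(sum(other$included), 0L)
})

test_that("HMM files and hit tables round-trip exactly", {
  model <- calibrate(tiny_model_library()[[2]], seed = 31)
  model$gathering_threshold <- 27.0
  tf <- tempfile(fileext = ".hmm")
  write_hmm(model, tf)
  back <- read_hmm(tf)
  expect_identical(back$match_emissions, model$match_emissions)
  expect_identical(back$transitions, model$transitions)
  expect_identical(back$calibration, model$calibration)
  expect_identical(back$background, model$background)
  expect_identical(back$gathering_threshold, model$gathering_threshold)
  expect_identical(back$name, model$name)

  hits <- find_domains(model, seq_set("x", paste0(
    "MKTA", consensus_sequence(model), "QRQS")), db_size = 3)
  hits$included <- TRUE
  th <- tempfile(fileext = ".tsv")
  write_hits(hits, th)
  back_h <- read_hits(th)
  expect_equal(back_h$env_from, hits$env_from)
  expect_equal(back_h$score_bits, hits$score_bits)
  expect_equal(back_h$included, hits$included)
})
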