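# Architecture classification: overlap resolution (with its brute-force
# oracle), signatures, class grouping, display filtering and the composite
# length split.

mk_hit <- function(clan, from, to, score, iev, model = clan) {
  data.frame(sequence_id = "s1", model = model, clan = clan,
             env_from = from, env_to = to, ali_from = from, ali_to = to,
             hmm_from = 1L, hmm_to = to - from + 1L,
             score_bits = score, i_evalue = iev, stringsAsFactors = FALSE)
}

# independent exhaustive reference: best conflict-free subset by summed bits
brute_force_resolution <- function(hits) {
  n <- nrow(hits)
  conflicts <- function(i, j) {
    if (hits$clan[i] != hits$clan[j]) return(FALSE)
    ov <- min(hits$env_to[i], hits$env_to[j]) -
      max(hits$env_from[i], hits$env_from[j]) + 1L
    if (ov <= 0L) return(FALSE)
    shorter <- min(hits$env_to[i] - hits$env_from[i],
                   hits$env_to[j] - hits$env_from[j]) + 1L
    ov > 0.5 * shorter
  }
  best <- NULL; best_score <- -Inf
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    ok <- TRUE
    if (length(sel) > 1) {
      for (a in seq_along(sel)) {
        for (b in seq_along(sel)) {
          if (a < b && conflicts(sel[a], sel[b])) ok <- FALSE
        }
      }
    }
    if (ok) {
      sc <- sum(hits$score_bits[sel])
      if (sc > best_score + 1e-12) { best_score <- sc; best <- sel }
    }
  }
  sort(best)
}

test_that("overlap resolution keeps the best of same-clan overlaps", {
  h <- rbind(mk_hit("WYL", 10, 100, 80, 1e-8, model = "WYL_a"),
             mk_hit("WYL", 15, 105, 40, 1e-3, model = "WYL_b"))
  r <- resolve_overlaps(h)
  expect_equal(nrow(r), 1L)
  expect_equal(r$model, "WYL_a")

  disjoint <- rbind(mk_hit("WYL", 10, 100, 80, 1e-8),
                    mk_hit("WCX", 120, 180, 50, 1e-6))
  expect_equal(nrow(resolve_overlaps(disjoint)), 2L)

  # cross-clan overlaps are retained
  cross <- rbind(mk_hit("WYL", 10, 100, 80, 1e-8),
                 mk_hit("WCX", 50, 120, 50, 1e-6))
  expect_equal(nrow(resolve_overlaps(cross)), 2L)
})

test_that("overlap resolution equals the brute-force subset optimum", {
  wyldomkit:::with_seed(404, {
    for (rep in 1:25) {
      n <- sample(2:4, 1)
      clans <- sample(c("WYL", "HTH"), n, replace = TRUE,
                      prob = c(0.8, 0.2))
      from <- sample(1:120, n)
      len <- sample(40:90, n, replace = TRUE)
      h <- do.call(rbind, lapply(seq_len(n), function(i) {
        mk_hit(clans[i], from[i], from[i] + len[i], runif(1, 20, 90),
               10^-runif(1, 3, 9), model = paste0(clans[i], "_m", i))
      }))
      r <- resolve_overlaps(h)
      expected <- brute_force_resolution(h)
      expect_setequal(r$model, h$model[expected])
      # output is conflict-free
      if (nrow(r) > 1) {
        for (a in 1:(nrow(r) - 1)) {
          for (b in (a + 1):nrow(r)) {
            expect_false(wyldomkit:::overlaps_conflict(r, a, b))
          }
        }
      }
    }
  })
})

test_that("signatures are ordered N to C and keep tandem repeats", {
  h <- rbind(mk_hit("HTH", 10, 80, 60, 1e-9),
             mk_hit("WYL", 120, 190, 70, 1e-10),
             mk_hit("WCX", 200, 270, 50, 1e-7))
  expect_equal(signature_of(h), c("HTH", "WYL", "WCX"))

  # nothing passes the cut -> unclassified
  weak <- mk_hit("WYL", 10, 80, 10, 0.5)
  expect_length(signature_of(weak), 0L)

  tandem <- rbind(mk_hit("HTH", 1, 60, 60, 1e-9),
                  mk_hit("WYL", 70, 150, 60, 1e-9),
                  mk_hit("WCX", 160, 230, 60, 1e-9),
                  mk_hit("HTH", 240, 300, 60, 1e-9),
                  mk_hit("WYL", 310, 390, 60, 1e-9),
                  mk_hit("WCX", 400, 470, 60, 1e-9))
  expect_equal(signature_of(tandem),
               c("HTH", "WYL", "WCX", "HTH", "WYL", "WCX"))
  # the cut is strict: exactly 0.01 fails
  at_cut <- mk_hit("WYL", 10, 80, 30, 0.01)
  expect_length(signature_of(at_cut, evalue_cut = 0.01), 0L)
})

test_that("class grouping computes the survey statistics", {
  proteins <- data.frame(
    sequence_id = paste0("p", 1:10),
    signature = "HTH+WYL+WCX",
    length = 100:109, stringsAsFactors = FALSE)
  cls <- group_classes(proteins)
  expect_equal(nrow(cls), 1L)
  expect_equal(cls$label, "A")
  expect_equal(cls$median_length, 104.5)  # midpoint rule for even counts
  expect_equal(cls$n_sequences, 10L)

  mixed <- data.frame(
    sequence_id = paste0("p", 1:10),
    signature = c(rep("HTH+WYL+WCX", 6), rep("HTH+WYL", 3), ""),
    length = c(330:335, 240:242, 500), stringsAsFactors = FALSE)
  cls2 <- group_classes(mixed)
  expect_equal(cls2$label, c("A", "B"))
  expect_equal(cls2$signature, c("HTH+WYL+WCX", "HTH+WYL"))
  expect_equal(sum(cls2$n_sequences), 9L)          # partition of classified
  expect_equal(attr(cls2, "unclassified"), "p10")

  # invariant to input order, labels stable
  cls3 <- group_classes(mixed[sample(10), ])
  expect_equal(cls3$signature, cls2$signature)
  expect_equal(cls3$n_sequences, cls2$n_sequences)
})

test_that("the display filter hides classes below the member floor", {
  classes <- group_classes(data.frame(
    sequence_id = paste0("p", 1:150),
    signature = c(rep("HTH+WYL+WCX", 51), rep("HTH+WYL", 99)),
    length = 300, stringsAsFactors = FALSE))
  shown <- filter_display_classes(classes)     # default floor 100
  expect_equal(nrow(shown), 0L)                # 99 and 51 both hidden
  expect_equal(nrow(filter_display_classes(classes, 1L)), 2L)
  expect_lte(sum(filter_display_classes(classes, 50L)$n_sequences),
             sum(classes$n_sequences))
})

test_that("composite hits split at the length threshold with ties short", {
  hits <- rbind(mk_hit("WYL", 10, 169, 80, 1e-9),    # length 160
                mk_hit("WYL", 10, 99, 60, 1e-9),     # length 90
                mk_hit("WYL", 10, 136, 60, 1e-9))    # length 127 -> short
  sp <- composite_length_split(hits, 127L)
  expect_equal(nrow(sp$long), 1L)
  expect_equal(nrow(sp$short), 2L)
  expect_setequal(c(sp$long$hit_id, sp$short$hit_id),
                  wyldomkit:::hit_ids(hits))
  all_equal <- composite_length_split(
    rbind(mk_hit("WYL", 1, 127, 60, 1e-9)), 127L)
  expect_equal(nrow(all_equal$short), 1L)
  expect_equal(nrow(all_equal$long), 0L)
})

test_that("proteome annotation is empty-safe and order-independent", {
  models <- tiny_model_library()
  empty <- annotate_proteome(models, seq_set(character(), character()))
  expect_equal(nrow(empty$hits), 0L)

  db <- wyldomkit:::with_seed(90, {
    seq_set(c("a", "b"),
            c(paste0(wyldomkit:::random_residues(20),
                     consensus_sequence(models[[1]]),
                     wyldomkit:::random_residues(20)),
              wyldomkit:::random_residues(120)))
  })
  fwd <- annotate_proteome(models, db)
  rev <- annotate_proteome(models, db[2:1, ])
  key <- function(a) a$hits[order(a$hits$sequence_id, a$hits$env_from),
                            c("sequence_id", "model", "env_from", "env_to")]
  expect_equal(key(fwd), key(rev), ignore_attr = TRUE)
})

test_that("clan maps are total and respect overrides", {
  models <- tiny_model_library()
  cm <- clan_map(models)
  expect_setequal(names(cm), vapply(models, `[[`, character(1), "name"))
  cm2 <- clan_map(models, overrides = c(alpha = "CL0123"))
  expect_equal(unname(cm2["alpha"]), "CL0123")
})

test_that("domain-free regions are reported, never reclassified", {
  models <- tiny_model_library()
  db <- wyldomkit:::with_seed(91, {
    seq_set("long_bg", wyldomkit:::random_residues(300))
  })
  ann <- annotate_proteome(models, db)
  regions <- domain_free_regions(ann, db, min_len = 80L)
  expect_gte(nrow(regions), 1L)
  expect_true(all(regions$length >= 80L))
})
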