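# Independent brute-force oracle for the profile-HMM engine: top-down
# recursion over every legal state path of the local multi-hit topology.
# Scores are recomputed here from the model's probability tables with the
# documented entry/exit/loop formulas, so the oracle shares no code with the
# iterative C++ DP it checks.

logsum2_r <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log2(1 + 2^(min(a, b) - m))
}

# memoize = FALSE walks the whole path tree (literal enumeration);
# memoize = TRUE caches (state, node, position) suffix values, computing the
# same max/log-sum top-down — used for the larger sweep sizes after the pure
# enumeration has validated it on smaller ones.
brute_force_scores <- function(model, residues, multihit = TRUE,
                               memoize = FALSE) {
  memo <- if (memoize) new.env(parent = emptyenv()) else NULL
  cached <- function(key, thunk) {
    if (is.null(memo)) return(thunk())
    if (!is.null(memo[[key]])) return(memo[[key]])
    memo[[key]] <- thunk()
    memo[[key]]
  }
  codes <- wyldomkit:::encode_residues(residues)
  L <- length(codes)
  M <- model$M
  bg <- model$background
  msc <- function(k, i) {
    x <- codes[i]
    if (x == 21L) 0 else log2(model$match_emissions[k, x] / bg[x])
  }
  tr <- model$transitions
  ek <- 1 / (M - seq_len(M) + 1)
  if (multihit) {
    loop <- log2(L / (L + 3)); move <- log2(3 / (L + 3))
    ej <- log2(0.5); ec <- log2(0.5)
  } else {
    loop <- log2(L / (L + 2)); move <- log2(2 / (L + 2))
    ej <- -Inf; ec <- 0
  }
  NEG <- c(-Inf, -Inf)
  comb <- function(a, b) c(max(a[1], b[1]), logsum2_r(a[2], b[2]))
  shift <- function(v, s) if (identical(v, NEG)) NEG else v + s

  from_C <- function(i) cached(paste0("C", i), function() {
    out <- if (i == L) c(move, move) else NEG
    if (i < L) out <- comb(out, shift(from_C(i + 1), loop))
    out
  })
  from_E <- function(i) cached(paste0("E", i), function() {
    out <- shift(from_C(i), ec)
    if (ej > -Inf) out <- comb(out, shift(from_J(i), ej))
    out
  })
  from_J <- function(i) cached(paste0("J", i), function() {
    out <- shift(from_B(i), move)
    if (i < L) out <- comb(out, shift(from_J(i + 1), loop))
    out
  })
  from_M <- function(k, i) cached(paste0("M", k, "_", i), function() {
    out <- shift(from_E(i), log2(ek[k]))
    if (k < M) {
      keep <- log2(1 - ek[k])
      if (i < L) {
        out <- comb(out, shift(from_M(k + 1, i + 1),
                               log2(tr[k + 1, "MM"]) + keep + msc(k + 1, i + 1)))
      }
      out <- comb(out, shift(from_D(k + 1, i), log2(tr[k + 1, "MD"]) + keep))
      if (i < L) {
        out <- comb(out, shift(from_I(k, i + 1), log2(tr[k + 1, "MI"]) + keep))
      }
    }
    out
  })
  from_I <- function(k, i) cached(paste0("I", k, "_", i), function() {
    out <- NEG
    if (k < M && i < L) {
      out <- comb(out, shift(from_M(k + 1, i + 1),
                             log2(tr[k + 1, "IM"]) + msc(k + 1, i + 1)))
    }
    if (i < L) out <- comb(out, shift(from_I(k, i + 1), log2(tr[k + 1, "II"])))
    out
  })
  from_D <- function(k, i) cached(paste0("D", k, "_", i), function() {
    out <- NEG
    if (k < M) {
      if (i < L) {
        out <- comb(out, shift(from_M(k + 1, i + 1),
                               log2(tr[k + 1, "DM"]) + msc(k + 1, i + 1)))
      }
      out <- comb(out, shift(from_D(k + 1, i), log2(tr[k + 1, "DD"])))
    }
    out
  })
  from_B <- function(i) cached(paste0("B", i), function() {
    out <- NEG
    if (i < L) {
      for (k in seq_len(M)) {
        out <- comb(out, shift(from_M(k, i + 1), log2(1 / M) + msc(k, i + 1)))
      }
    }
    out
  })
  from_N <- function(i) cached(paste0("N", i), function() {
    out <- shift(from_B(i), move)
    if (i < L) out <- comb(out, shift(from_N(i + 1), loop))
    out
  })
  null <- L * log2(L / (L + 1)) + log2(1 / (L + 1))
  res <- from_N(0) - null
  list(viterbi = res[1], forward = res[2])
}

# small random profile over a reduced alphabet, built through build_profile
random_tiny_model <- function(M, seed, alphabet = c("A", "C", "D", "E")) {
  wyldomkit:::with_seed(seed, {
    rows <- vapply(1:4, function(r) {
      paste(sample(alphabet, M, replace = TRUE), collapse = "")
    }, character(1))
    build_profile(msa(paste0("r", 1:4), rows), name = paste0("tiny", M))
  })
}

random_tiny_seq <- function(L, seed, alphabet = c("A", "C", "D", "E")) {
  wyldomkit:::with_seed(seed, paste(sample(alphabet, L, replace = TRUE),
                                    collapse = ""))
}
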