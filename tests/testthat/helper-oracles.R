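# Independent oracles and small fixture builders shared across tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# set-membership consensus oracle, written independently of match_consensus
consensus_oracle <- function(tri) {
  ch <- strsplit(tri, "")[[1]]
  (ch[1] %in% c("A", "S", "C", "N", "P", "H", "T", "G")) &&
    (ch[2] %in% c("R", "K", "H", "Q", "N", "S", "L")) &&
    (ch[3] %in% c("L", "M", "I", "V", "F"))
}

# naive per-position loop implementation of the windowed-hydropathy profile,
# independent of the package's vectorised version
KD_TABLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

naive_tm_oracle <- function(seq, window = 19, threshold = 1.6, min_run = 15) {
  ch <- strsplit(seq, "")[[1]]
  kd <- unname(KD_TABLE[ch])
  kd[is.na(kd)] <- 0
  n <- length(ch)
  half <- (window - 1) / 2
  prop <- integer(n)
  for (i in seq_len(n)) {
    w <- kd[max(1, i - half):min(n, i + half)]
    prop[i] <- as.integer(mean(w) >= threshold)
  }
  # zero out runs shorter than min_run
  segs <- list()
  i <- 1
  while (i <= n) {
    if (prop[i] == 1) {
      j <- i
      while (j < n && prop[j + 1] == 1) j <- j + 1
      if (j - i + 1 >= min_run) {
        segs[[length(segs) + 1]] <- c(i - 1, j)  # 0-based half-open
      } else {
        prop[i:j] <- 0
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  list(prop = prop, exp_aa = sum(prop),
       exp_aa_60 = sum(prop[seq_len(min(60, n))]), segments = segs)
}

# a bundled-pool 12-mer known to be scored TARGETED (checked in tests)
targeted_tail <- function() "TGLLSVAAGSKL"
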