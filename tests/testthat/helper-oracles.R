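# Brute-force oracles for the sequence detectors, kept deliberately naive:
# they enumerate every window / adjacent pair instead of sharing any code
# with the package implementation.

ROWSETS <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
COLSETS <- list(c(1, 4, 7), c(2, 5, 8), c(3, 6, 9))

oracle_encoding <- function(aoi_seq) {
  row <- col <- FALSE
  n <- length(aoi_seq)
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      w <- aoi_seq[i:(i + 2)]
      if (any(is.na(w)) || any(w > 9)) next
      for (s in ROWSETS) if (setequal(w, s)) row <- TRUE
      for (s in COLSETS) if (setequal(w, s)) col <- TRUE
    }
  }
  c(row = row, col = col)
}

oracle_toggles <- function(aoi_seq) {
  a <- aoi_seq[!is.na(aoi_seq)]
  # collapse consecutive repeats
  if (length(a) > 1) a <- a[c(TRUE, diff(a) != 0)]
  n <- 0L
  if (length(a) >= 2) {
    for (i in 1:(length(a) - 1)) {
      if ((a[i] <= 9 && a[i + 1] == 10) || (a[i] == 10 && a[i + 1] <= 9))
        n <- n + 1L
    }
  }
  n
}

random_aoi_seq <- function(max_len = 40, p_na = 0.1) {
  n <- sample(0:max_len, 1)
  s <- sample(1:10, n, replace = TRUE)
  s[runif(n) < p_na] <- NA
  s
}

# small fixation data frame from paired (aoi, duration) vectors
fix_df <- function(aoi, duration, onset = cumsum(c(0, head(duration, -1)))) {
  data.frame(onset = onset, duration = duration, aoi = aoi)
}

# stationary raw samples at a given point
still_samples <- function(n, x = 300, y = 200, t0 = 0, rate = 50,
                          jitter = 0) {
  data.frame(t = t0 + (seq_len(n) - 1) / rate,
             x = x + rnorm(n, 0, jitter), y = y + rnorm(n, 0, jitter),
             valid = TRUE)
}
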