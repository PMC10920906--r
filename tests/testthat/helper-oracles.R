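# Independent oracles, deliberately naive: these re-derive expected values
# by brute force or closed form and must stay free of package internals.

# MSD by explicit double loop over all ordered pairs of one trajectory
msd_brute_force <- function(t_s, x, y, dt) {
  n <- length(t_s)
  kmax <- n - 1
  res <- data.frame(lag_s = numeric(), msd = numeric(), n_pairs = integer())
  for (k in seq_len(kmax)) {
    acc <- c()
    for (i in seq_len(n - k)) {
      acc <- c(acc, (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
    }
    res <- rbind(res, data.frame(lag_s = k * dt, msd = mean(acc),
                                 n_pairs = length(acc)))
  }
  res
}

# motif count by sliding a character window, both strands, overlapping
count_sites_window <- function(seq, motif = "CCGC", both_strands = TRUE) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  targets <- motif
  if (both_strands && revcomp(motif) != motif) targets <- c(motif, revcomp(motif))
  chars <- strsplit(seq, "")[[1]]
  m <- nchar(motif)
  total <- 0L
  for (tg in targets) {
    tchars <- strsplit(tg, "")[[1]]
    if (length(chars) >= m) {
      for (i in seq_len(length(chars) - m + 1)) {
        if (all(chars[i:(i + m - 1)] == tchars)) total <- total + 1L
      }
    }
  }
  total
}

# classical closed forms for the two-sample statistics
paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, p = 2 * pt(-abs(t), n - 1))
}

pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, p = 2 * pt(-abs(t), na + nb - 2))
}

anova_f_oracle <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# hard-edged discs on a dark background (no noise, no soft edge)
disc_image <- function(h, w, centers, radius, fg = 100, bg = 0) {
  img <- matrix(bg, h, w)
  for (r in seq_len(nrow(centers))) {
    for (yy in seq_len(h)) {
      for (xx in seq_len(w)) {
        if ((yy - 1 - centers[r, 1])^2 + (xx - 1 - centers[r, 2])^2 <=
            radius^2) img[yy, xx] <- fg
      }
    }
  }
  img
}

# amplicon with an exact number of AciI sites on the given strand and no
# reverse-strand sites; synthetic construction, not a genomic sequence
make_amplicon_with_sites <- function(n_sites, fwd = "ACTGACTGACTGACTGAATT",
                                     rev = "TTCATTCATTCATTCATTCA") {
  spacer <- "ATTATA"
  core <- paste(rep(paste0("CCGC", spacer), n_sites), collapse = "")
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  paste0(fwd, spacer, core, revcomp(rev))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
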