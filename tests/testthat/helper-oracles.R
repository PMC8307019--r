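## Independent oracles used to cross-check the implementation. These stay
## deliberately naive: explicit loops and lattice searches, no shared code
## with the package internals.

## per-pixel loop applying the ellipse inequality (boundary included)
bruteForceROI <- function(px, center, semi_axes) {
  vals <- c()
  for (r in seq_len(nrow(px))) {
    for (cc in seq_len(ncol(px))) {
      d <- ((r - center[1]) / semi_axes[1])^2 + ((cc - center[2]) / semi_axes[2])^2
      if (d <= 1) vals <- c(vals, px[r, cc])
    }
  }
  vals
}

## closed-form OLS of y on x
olsOracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

## exhaustive lattice search minimising the RSS of s0*exp(-te/t2)+c
gridSearchDecay <- function(te, s, t2_grid, s0_grid, c_grid) {
  best <- list(rss = Inf)
  for (t2 in t2_grid) {
    e <- exp(-te / t2)
    for (s0 in s0_grid) {
      base <- s - s0 * e
      for (c0 in c_grid) {
        rss <- sum((base - c0)^2)
        if (rss < best$rss) best <- list(rss = rss, t2 = t2, s0 = s0, c0 = c0)
      }
    }
  }
  best
}

## small constant frame for geometry tests
constFrame <- function(value, nr = 16, nc = 16, role = "T1_MAP") {
  ImageFrame(pixels = matrix(value, nr, nc), role = role)
}
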