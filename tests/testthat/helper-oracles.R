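# Independent reference implementations used to check package routines.
# These deliberately use different code paths from the package.

# percentile by explicit sort + closest-rank linear interpolation:
# rank r = 1 + (n - 1) * X / 100
oracle_percentile <- function(values, X) {
  v <- sort(values)
  n <- length(v)
  r <- 1 + (n - 1) * X / 100
  lo <- floor(r); hi <- ceiling(r)
  v[lo] + (r - lo) * (v[hi] - v[lo])
}

# AUROC via the Mann-Whitney U statistic of stats::wilcox.test (average
# ranks give the half-credit tie convention)
oracle_auroc <- function(pos, neg) {
  w <- suppressWarnings(stats::wilcox.test(pos, neg, exact = FALSE))
  unname(w$statistic) / (length(pos) * length(neg))
}

# exhaustive Youden search over all candidate thresholds with the package's
# stated tie rules (higher specificity, then lower threshold)
oracle_youden <- function(pos, neg) {
  thr <- c(-Inf, sort(unique(c(pos, neg))))
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(abs(j - max(j)) < 1e-12)
  best <- best[order(-spec[best], thr[best])][1]
  list(t_opt = thr[best], j = j[best], sensitivity = sens[best],
       specificity = spec[best])
}

# brute-force ASSD: explicit 6-neighbour surface detection and full pairwise
# world distances
oracle_assd <- function(selA, selB, spacing) {
  surface <- function(sel) {
    d <- dim(sel)
    pts <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!sel[i, j, k]) next
      nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                  c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
      outside <- apply(nb, 1, function(x)
        any(x < 1) || any(x > d) || !sel[x[1], x[2], x[3]])
      if (any(outside)) pts <- rbind(pts, c(i, j, k))
    }
    sweep(pts - 1, 2, spacing, "*")
  }
  A <- surface(selA); B <- surface(selB)
  dmin <- function(P, Q) mean(apply(P, 1, function(p)
    min(sqrt(colSums((t(Q) - p)^2)))))
  (dmin(A, B) + dmin(B, A)) / 2
}

# small test mask: 8x8x8 at 2 mm with a bowel block, a lung slab and a
# thyroid voxel pair
toy_mask <- function() {
  g <- imageGrid(c(8, 8, 8), spacing = 2)
  lab <- array(0L, c(8, 8, 8))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[6:7, 1:8, 1:4] <- 2L
  lab[6:7, 2, 7] <- 3L
  organMask(lab, g)
}

# quick coarse phantom shared across tests (built once per test run)
test_phantom_mask <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(buildPhantom(phantomSpec(spacing = 8)))
    cache
  }
})

# fast, quiet uptake model for event-pattern tests
quiet_model <- function(...) {
  uptakeModel(patient_sd = c(bowel = 0, lung = 0, thyroid = 0),
              bg_sd = 0, noise_sd = 0, ...)
}
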