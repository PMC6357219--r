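# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms and share no code with R/.

# Grayscale opening with an explicit spherical-cap ball element: min-then-max
# over all offsets inside the disc, out-of-image offsets ignored.
oracleBallOpening <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  offs$h <- sqrt(r^2 - offs$dy^2 - offs$dx^2)
  pass <- function(f, dilate) {
    out <- matrix(if (dilate) -Inf else Inf, H, W)
    for (i in seq_len(nrow(offs))) {
      dy <- offs$dy[i]; dx <- offs$dx[i]; h <- offs$h[i]
      ys <- max(1, 1 - dy):min(H, H - dy)
      xs <- max(1, 1 - dx):min(W, W - dx)
      sub <- f[ys + dy, xs + dx, drop = FALSE]
      v <- if (dilate) sub + h else sub - h
      out[ys, xs] <- if (dilate) pmax(out[ys, xs], v) else pmin(out[ys, xs], v)
    }
    out
  }
  pass(pass(img, FALSE), TRUE)
}

# 8-connected components by breadth-first flood fill; returns a list of
# sorted linear pixel index vectors, ordered by smallest member.
oracleFloodFill8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  comps <- list()
  for (start in which(mask)) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      comp <- c(comp, p)
      r <- (p - 1) %% H + 1; cc <- (p - 1) %/% H + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr < 1 || rr > H || ccc < 1 || ccc > W) next
        q <- (ccc - 1) * H + rr
        if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
    comps[[length(comps) + 1]] <- sort(as.integer(comp))
  }
  comps[order(vapply(comps, min, 1L))]
}

# Run-length scanner over a NORMAL/PVC label string, walking element by
# element (no rle).
oracleRuns <- function(labels) {
  out <- data.frame(start_index = integer(0), length = integer(0),
                    category = character(0), stringsAsFactors = FALSE)
  i <- 1L; n <- length(labels)
  while (i <= n) {
    if (labels[i] == "PVC") {
      j <- i
      while (j < n && labels[j + 1L] == "PVC") j <- j + 1L
      len <- j - i + 1L
      cat <- if (len >= 4) "TACHYCARDIA" else if (len >= 2) "SALVO" else "SINGLE"
      out <- rbind(out, data.frame(start_index = i, length = len,
                                   category = cat, stringsAsFactors = FALSE))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, summing hypergeometric probabilities no larger than the observed
# table's.
oracleFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  pr <- vapply(lo:hi, function(x)
    exp(lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)), 0)
  pObs <- pr[a - lo + 1]
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values into the two groups; U counted pairwise (ties count half).
oracleMannWhitneyP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  uOf <- function(xs, ys)
    sum(vapply(xs, function(v) sum(v > ys) + 0.5 * sum(v == ys), 0))
  uObs <- uOf(x, y)
  mu <- n1 * n2 / 2
  sel <- utils::combn(n1 + n2, n1)
  us <- apply(sel, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}
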