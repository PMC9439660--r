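# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

# Concordance by exhaustive pair enumeration.
cstat_enum <- function(time, event, score) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  num / den
}

# Two-group log-rank chi-square by the O-E / V tally at each event time.
logrank_hand <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L   # 0/1
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t0 in ev_times) {
    at_risk <- time >= t0
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Cox partial likelihood (Breslow; exact for untied times) maximized
# numerically, independent of any Cox fitting routine.
cox_newton_oracle <- function(time, event, X) {
  X <- as.matrix(X)
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    s <- 0
    for (i in which(event == 1))
      s <- s - eta[i] + log(sum(exp(eta[time >= time[i]])))
    s
  }
  stats::optim(rep(0, ncol(X)), nll, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))$par
}

# Majority filter + small-component absorption, re-implemented with plain
# scans and row-major flood fill.
naive_smooth <- function(labels, min_region = 2) {
  nr <- nrow(labels); nc <- ncol(labels)
  maj <- labels
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(labels[i, j])) next
    vals <- character(0)
    for (di in -1:1) for (dj in -1:1) {
      y <- i + di; x <- j + dj
      if (y >= 1 && y <= nr && x >= 1 && x <= nc && !is.na(labels[y, x]))
        vals <- c(vals, labels[y, x])
    }
    tb <- table(vals)
    mx <- names(tb)[tb == max(tb)]
    maj[i, j] <- if (length(mx) == 1) mx else labels[i, j]
  }
  for (pass in 1:10) {
    comp <- matrix(0L, nr, nc); k <- 0L
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (is.na(maj[i, j]) || comp[i, j] != 0L) next
      k <- k + 1L
      stack <- list(c(i, j)); comp[i, j] <- k
      while (length(stack)) {
        cur <- stack[[1]]; stack <- stack[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          y <- cur[1] + d[1]; x <- cur[2] + d[2]
          if (y >= 1 && y <= nr && x >= 1 && x <= nc && comp[y, x] == 0L &&
              !is.na(maj[y, x]) && maj[y, x] == maj[i, j]) {
            comp[y, x] <- k
            stack <- c(stack, list(c(y, x)))
          }
        }
      }
    }
    sizes <- tabulate(comp)
    small <- which(sizes > 0 & sizes < min_region)
    if (!length(small)) break
    base <- maj
    changed <- FALSE
    for (cid in small) {
      cells <- which(comp == cid, arr.ind = TRUE)
      nbids <- integer(0)
      for (r in seq_len(nrow(cells)))
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          y <- cells[r, 1] + d[1]; x <- cells[r, 2] + d[2]
          if (y >= 1 && y <= nr && x >= 1 && x <= nc && comp[y, x] != 0L &&
              comp[y, x] != cid)
            nbids <- c(nbids, comp[y, x])
        }
      if (!length(nbids)) next
      nbids <- unique(nbids)
      frm <- vapply(nbids, function(id) {
        cc <- which(comp == id, arr.ind = TRUE)
        min((cc[, 1] - 1) * nc + (cc[, 2] - 1))
      }, numeric(1))
      best <- nbids[order(-sizes[nbids], frm)][1]
      maj[comp == cid] <- base[which(comp == best)[1]]
      changed <- TRUE
    }
    if (!changed) break
  }
  maj
}

# Number of 4-connected same-label components (background excluded).
count_components <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  seen <- matrix(FALSE, nr, nc); k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(labels[i, j]) || seen[i, j]) next
    k <- k + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      cur <- stack[[1]]; stack <- stack[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        y <- cur[1] + d[1]; x <- cur[2] + d[2]
        if (y >= 1 && y <= nr && x >= 1 && x <= nc && !seen[y, x] &&
            !is.na(labels[y, x]) && labels[y, x] == labels[i, j]) {
          seen[y, x] <- TRUE
          stack <- c(stack, list(c(y, x)))
        }
      }
    }
  }
  k
}

# Angle-averaged GLCM contrast by explicit pair tallying.
glcm_contrast_hand <- function(gray, levels = 32) {
  q <- pmin(floor(gray / 256 * levels), levels - 1) + 1
  H <- nrow(q); W <- ncol(q)
  vals <- sapply(list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)), function(o) {
    cnt <- matrix(0, levels, levels)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      y <- i + o[1]; x <- j + o[2]
      if (y >= 1 && y <= H && x >= 1 && x <= W) {
        cnt[q[i, j], q[y, x]] <- cnt[q[i, j], q[y, x]] + 1
        cnt[q[y, x], q[i, j]] <- cnt[q[y, x], q[i, j]] + 1
      }
    }
    p <- cnt / sum(cnt)
    s <- 0
    for (a in seq_len(levels)) for (b in seq_len(levels))
      s <- s + p[a, b] * (a - b)^2
    s
  })
  mean(vals)
}

# Plain (uncensored) ROC AUC by rank statistic.
plain_auc <- function(y, score) {
  pos <- score[y == 1]; neg <- score[y == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}
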