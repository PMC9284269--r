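# Independent brute-force oracles, kept deliberately naive (explicit
# loops, no shared code with the implementation) so agreement is
# meaningful.

naive_dissimilarity <- function(x) {
  n <- nrow(x); p <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (s in seq_len(p)) {
      rng <- max(x[, s]) - min(x[, s])
      if (rng > 0) acc <- acc + abs(x[i, s] - x[j, s]) / rng
    }
    d[i, j] <- acc
  }
  d
}

naive_density <- function(d, r, active = seq_len(nrow(d))) {
  out <- integer(length(active))
  for (a in seq_along(active)) {
    cnt <- 0L
    for (j in active) if (d[active[a], j] <= r) cnt <- cnt + 1L
    out[a] <- cnt
  }
  out
}

naive_alpha <- function(d, r, i, active = seq_len(nrow(d))) {
  nb <- c()
  for (j in active) if (d[i, j] <= r) nb <- c(nb, j)
  if (length(nb) <= 1) return(0)
  acc <- 0
  for (u in nb) for (v in nb) acc <- acc + d[u, v]
  acc / length(nb)^2
}

naive_s <- function(d, rho, i, active = seq_len(nrow(d))) {
  if (length(active) == 1) return(0)
  pos <- which(active == i)
  higher <- c()
  for (a in seq_along(active))
    if (a != pos && rho[a] > rho[pos]) higher <- c(higher, active[a])
  if (length(higher)) min(d[i, higher]) else max(d[i, active[-pos]])
}

# pair-based metrics by explicit enumeration of all point pairs
naive_pair_metrics <- function(truth, pred) {
  n <- length(truth)
  agree <- 0; tp <- 0; pos_pred <- 0; pos_truth <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st == sp) agree <- agree + 1
    if (st && sp) tp <- tp + 1
    if (sp) pos_pred <- pos_pred + 1
    if (st) pos_truth <- pos_truth + 1
  }
  total <- n * (n - 1) / 2
  prec <- if (pos_pred > 0) tp / pos_pred else 0
  rec <- if (pos_truth > 0) tp / pos_truth else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec)
       else if (pos_pred == 0 && pos_truth == 0) 1 else 0
  list(rand = agree / total, f = f)
}

naive_nmi <- function(truth, pred) {
  tu <- unique(truth); pu <- unique(pred)
  n <- length(truth)
  hu <- 0
  for (u in tu) { p <- sum(truth == u) / n; hu <- hu - p * log(p) }
  hv <- 0
  for (v in pu) { p <- sum(pred == v) / n; hv <- hv - p * log(p) }
  if (hu == 0 && hv == 0) return(1)
  mi <- 0
  for (u in tu) for (v in pu) {
    puv <- sum(truth == u & pred == v) / n
    if (puv > 0)
      mi <- mi + puv * log(puv / ((sum(truth == u) / n) * (sum(pred == v) / n)))
  }
  mi / ((hu + hv) / 2)
}

# mapped accuracy by exhaustive enumeration of one-to-one assignments
naive_accuracy <- function(truth, pred) {
  tu <- sort(unique(as.character(truth))); pu <- sort(unique(as.character(pred)))
  k <- max(length(tu), length(pu))
  cnt <- matrix(0, k, k)
  for (i in seq_along(truth)) {
    u <- match(as.character(truth[i]), tu)
    v <- match(as.character(pred[i]), pu)
    cnt[u, v] <- cnt[u, v] + 1
  }
  perms <- all_perms(k)
  best <- 0
  for (row in seq_len(nrow(perms))) {
    tot <- 0
    for (u in seq_len(k)) tot <- tot + cnt[u, perms[row, u]]
    best <- max(best, tot)
  }
  best / length(truth)
}

all_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_perms(k - 1)
  out <- NULL
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

naive_mtx_densify <- function(i, j, v, nr, nc) {
  m <- matrix(0, nr, nc)
  for (t in seq_along(i)) m[i[t], j[t]] <- m[i[t], j[t]] + v[t]
  m
}

# small random labeled instance for metric property tests
random_labels <- function(n, k) sample(seq_len(k), n, replace = TRUE)

# the 4-point worked example used throughout
toy_x <- function() cbind(c(0, 1, 4, 5))
toy_d <- function() matrix(c(0, .2, .8, 1,
                             .2, 0, .6, .8,
                             .8, .6, 0, .2,
                             1, .8, .2, 0), 4, 4, byrow = TRUE)
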