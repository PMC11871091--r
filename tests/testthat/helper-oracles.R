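# Independent brute-force oracles for the segmentation metrics. These are
# deliberately naive (explicit loops / all-pairs distances) and share no code
# with the package implementations they check.

oracle_dsc <- function(a, b, k) {
  na <- 0L; nb <- 0L; ni <- 0L
  for (p in seq_along(a)) {
    ia <- a[p] == k; ib <- b[p] == k
    na <- na + ia; nb <- nb + ib; ni <- ni + (ia && ib)
  }
  if (na + nb == 0) return(NA_real_)
  100 * 2 * ni / (na + nb)
}

oracle_sens_spec <- function(truth, pred, k) {
  tp <- fn <- tn <- fp <- 0L
  for (p in seq_along(truth)) {
    it <- truth[p] == k; ip <- pred[p] == k
    if (it && ip) tp <- tp + 1L
    else if (it && !ip) fn <- fn + 1L
    else if (!it && !ip) tn <- tn + 1L
    else fp <- fp + 1L
  }
  c(if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

# boundary: class pixel with a non-class 4-neighbour (border = non-class)
oracle_boundary <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  out <- NULL
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (m[i, j] != k) next
    nb <- c(if (i > 1) m[i - 1, j] else -1L,
            if (i < H) m[i + 1, j] else -1L,
            if (j > 1) m[i, j - 1] else -1L,
            if (j < W) m[i, j + 1] else -1L)
    if (any(nb != k)) out <- rbind(out, c(i, j))
  }
  out
}

oracle_assd <- function(a, b, k, spacing = c(1, 1)) {
  ba <- oracle_boundary(a, k); bb <- oracle_boundary(b, k)
  if (is.null(ba) || is.null(bb)) return(NA_real_)
  dmat <- outer(seq_len(nrow(ba)), seq_len(nrow(bb)), function(i, j) {
    sqrt(((ba[i, 1] - bb[j, 1]) * spacing[1])^2 +
           ((ba[i, 2] - bb[j, 2]) * spacing[2])^2)
  })
  mean(c(mean(apply(dmat, 1, min)), mean(apply(dmat, 2, min))))
}

# random blobby mask pair on an n x n grid (a few dilated seed points)
random_mask_pair <- function(n = 32, n_classes = 3) {
  blob <- function() {
    m <- matrix(0L, n, n)
    for (k in seq_len(n_classes)) {
      ctr <- cbind(sample(n, 2, replace = TRUE), sample(n, 2, replace = TRUE))
      r <- sample(2:max(3, n %/% 6), 1)
      i <- matrix(seq_len(n), n, n)
      j <- t(i)
      for (s in 1:2) {
        sel <- (i - ctr[s, 1])^2 + (j - ctr[s, 2])^2 <= r^2
        m[sel] <- k
      }
    }
    m
  }
  list(a = blob(), b = blob())
}
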