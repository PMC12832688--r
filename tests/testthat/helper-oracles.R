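# Independent oracles used to cross-check the implementation. Each is
# written from first principles (loops/pair counts), deliberately not
# sharing code with the package internals it checks.

# Longhand classification-report calculator from the four counts.
oracle_report <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  prec_p <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec_p <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec_n <- if (tn + fn > 0) tn / (tn + fn) else 0
  rec_n <- if (tn + fp > 0) tn / (tn + fp) else 0
  hm <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  f1_p <- hm(prec_p, rec_p); f1_n <- hm(prec_n, rec_n)
  sup_p <- tp + fn; sup_n <- fp + tn
  list(accuracy = (tp + tn) / n,
       precision = c(normal = prec_n, pneumonia = prec_p),
       recall = c(normal = rec_n, pneumonia = rec_p),
       f1 = c(normal = f1_n, pneumonia = f1_p),
       macro = c(precision = (prec_n + prec_p) / 2,
                 recall = (rec_n + rec_p) / 2,
                 f1 = (f1_n + f1_p) / 2),
       weighted = c(
         precision = (sup_n * prec_n + sup_p * prec_p) / n,
         recall = (sup_n * rec_n + sup_p * rec_p) / n,
         f1 = (sup_n * f1_n + sup_p * f1_p) / n))
}

# Mann-Whitney pair-counting AUC estimator, ties counted one half.
oracle_auc_paircount <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Expand a 2-D kernel by inserting (r-1) zero rows/columns between taps.
dilate_kernel <- function(k, r) {
  m <- nrow(k)
  out <- matrix(0, (m - 1) * r + 1, (m - 1) * r + 1)
  for (i in seq_len(m)) for (j in seq_len(m))
    out[(i - 1) * r + 1, (j - 1) * r + 1] <- k[i, j]
  out
}

# Plain dense valid-mode 2-D convolution (correlation), direct loops.
oracle_conv2d_valid <- function(x, k) {
  m <- nrow(k); H <- nrow(x) - m + 1; W <- ncol(x) - m + 1
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sum(x[i:(i + m - 1), j:(j + m - 1)] * k)
  out
}

expect_shape <- function(x, shape) expect_equal(dim(x), as.integer(shape))
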