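# Independent least-squares projection oracle for the split-plot ANCOVA:
# between stratum on subject means, within stratum on orthonormal time
# contrasts, Type III SS by residual-sum-of-squares differences under
# sum-to-zero coding with centered covariates.
anova_oracle <- function(wide, Y) {
  n <- nrow(wide)
  g <- ifelse(wide$group == levels(factor(wide$group))[1], 1, -1)
  covs <- scale(as.matrix(wide[, c("age", "gender", "education")]),
                scale = FALSE)
  Xb <- cbind(1, g, covs)
  p <- ncol(Xb)
  rss <- function(X, y) sum(lm.fit(as.matrix(X), y)$residuals^2)
  m <- rowMeans(Y)
  F_group <- ((rss(Xb[, -2], m) - rss(Xb, m)) / 1) / (rss(Xb, m) / (n - p))
  C <- qr.Q(qr(cbind(1, stats::contr.poly(ncol(Y)))))[, -1, drop = FALSE]
  Yc <- Y %*% C
  q <- ncol(C)
  SS_t <- SS_gt <- RSSw <- 0
  for (j in seq_len(q)) {
    f <- rss(Xb, Yc[, j])
    SS_t <- SS_t + rss(Xb[, -1], Yc[, j]) - f
    SS_gt <- SS_gt + rss(Xb[, -2], Yc[, j]) - f
    RSSw <- RSSw + f
  }
  dfe <- q * (n - p)
  list(F_time = (SS_t / q) / (RSSw / dfe),
       F_int = (SS_gt / q) / (RSSw / dfe),
       F_group = F_group)
}

make_long <- function(wide, Y) {
  do.call(rbind, lapply(seq_len(ncol(Y)), function(t)
    cbind(wide, timepoint = paste0("TP", t), y = Y[, t])))
}

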