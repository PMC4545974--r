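# Shared fixtures and independent oracles, built in code at test time.

# Static-head marker recording around a programmed lower-lip z trace.
static_rec <- function(z_lower, sample_rate = 250, z_upper = NULL,
                       pid = "p", tid = "t") {
  n <- length(z_lower)
  if (is.null(z_upper)) z_upper <- rep(33, n)
  fix <- function(p) matrix(rep(p, each = n), n, 3)
  marker_recording(pid, tid, sample_rate, list(
    upper_lip = cbind(rep(30, n), rep(-20, n), z_upper),
    lower_lip = cbind(rep(30, n), rep(-20, n), z_lower),
    head_1 = fix(c(0, 0, 50)), head_2 = fix(c(60, 5, 55)),
    head_3 = fix(c(30, 40, 62))))
}

# Head-frame -> filter -> differentiate -> segment, as the pipeline runs it.
pipe_segment <- function(rec, cfg = default_config()) {
  artikin:::process_trial(rec, cfg)
}

# Independent brute-force LA-index oracle: plain loops, no shared code
# with la_index() beyond stats::spline for the interpolant definition.
brute_la <- function(signals, n_points = 1000L) {
  mats <- matrix(NA_real_, length(signals), n_points)
  for (i in seq_along(signals)) {
    x <- signals[[i]]
    y <- stats::spline(seq(0, 1, length.out = length(x)), x,
                       xout = seq(0, 1, length.out = n_points),
                       method = "fmm")$y
    m <- sum(y) / n_points
    s <- sqrt(sum((y - m)^2) / n_points)
    mats[i, ] <- (y - m) / s
  }
  idx <- round((1:50) * n_points / 50)
  total <- 0
  prof <- numeric(50)
  for (j in seq_along(idx)) {
    col <- mats[, idx[j]]
    mu <- mean(col)
    prof[j] <- sqrt(sum((col - mu)^2) / (length(col) - 1))
    total <- total + prof[j]
  }
  list(la = total, profile = prof)
}

# Write a small marker trajectory table to a temp file and return path.
write_traj_fixture <- function(n = 4, rate = 250, time = NULL,
                               drop_col = NULL, sep = "\t") {
  tt <- if (is.null(time)) (seq_len(n) - 1) / rate else time
  n <- length(tt)
  df <- data.frame(time_s = tt)
  for (m in c("upper_lip", "lower_lip", "head_1", "head_2", "head_3")) {
    for (ax in c("x", "y", "z"))
      df[[paste0(m, "_", ax)]] <- round(rnorm(n, 10), 4)
  }
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
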