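# Shared fixtures, built once per test run.

# a quiet, fast muscle model for single-sweep tests
quiet_model <- function(...) {
  muscle_model(emg_noise_sd = 0, acc_noise_sd = 0, ...)
}

# small mixed cohort (2 healthy x 2 positions + 1 patient x 2 days = 6
# sessions) shared by the feature/classification/therapy tests
small_spec <- function() {
  cohort_spec(n_healthy = 2, n_patients = 1, positions_healthy = c(0, 4),
              seed = 402)
}

.fx_cache <- new.env(parent = emptyenv())

small_tables <- function() {
  if (is.null(.fx_cache$tables))
    .fx_cache$tables <- build_study_tables(small_spec(), seed = 421)
  .fx_cache$tables
}

# linearly separable toy classification problem: class shifts the mean of
# every feature by a large margin relative to noise
separable_features <- function(n_subjects = 4, events_per_subject = 30,
                               n_classes = 2, seed = 1) {
  set.seed(seed)
  n <- n_subjects * events_per_subject
  cls <- sample(seq_len(n_classes) - 1L, n, replace = TRUE)
  x <- tibble::tibble(
    fA = cls * 10 + rnorm(n),
    fB = -cls * 8 + rnorm(n),
    fC = rnorm(n))
  list(x = x, labels = cls,
       subjects = rep(paste0("S", seq_len(n_subjects)),
                      each = events_per_subject))
}

# class grid helper: four muscles at given positions/currents, labels
# filled from a function(position, current, muscle)
make_grid <- function(positions, currents, label_fn) {
  g <- tidyr::expand_grid(position = positions, current = currents,
                          muscle = c("Q_left", "Q_right", "TS_left",
                                     "TS_right"))
  g$label <- mapply(label_fn, g$position, g$current, g$muscle)
  g
}

# brute-force oracles -------------------------------------------------

# per-class recall averaging, written independently of the implementation
oracle_balanced_accuracy <- function(y_true, y_pred) {
  recalls <- c()
  for (k in unique(sort(y_true))) {
    idx <- y_true == k
    recalls <- c(recalls, sum(y_pred[idx] == k) / sum(idx))
  }
  sum(recalls) / length(recalls)
}

# recursive discrete Frechet distance with memoisation (textbook form)
oracle_frechet <- function(p, q) {
  n <- nrow(p); m <- nrow(q)
  memo <- matrix(NA_real_, n, m)
  dd <- function(i, j) sqrt(sum((p[i, ] - q[j, ])^2))
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == 1 && j == 1) dd(1, 1)
    else if (j == 1) max(rec(i - 1, 1), dd(i, 1))
    else if (i == 1) max(rec(1, j - 1), dd(1, j))
    else max(min(rec(i - 1, j), rec(i - 1, j - 1), rec(i, j - 1)), dd(i, j))
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# naive sliding median with reflection padding
oracle_running_median <- function(x, kernel) {
  n <- length(x)
  h <- (kernel - 1) / 2
  xp <- c(rev(x[2:(h + 1)]), x, rev(x[(n - h):(n - 1)]))
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- median(xp[i:(i + kernel - 1)])
  x - out
}
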