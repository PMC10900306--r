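# Brute-force oracles, deliberately independent of the package's
# interval-arithmetic implementations.

# Day-set era oracle: mark exposed days on a bitmap, close uncovered gaps of
# at most gap_days between exposed runs, keep runs of at least min_days.
oracle_eras <- function(start, end, gap_days = 30L, min_days = 5L,
                        horizon = 2000L) {
  lo <- min(start)
  days <- rep(FALSE, max(end) - lo + 1L)
  for (i in seq_along(start)) days[(start[i] - lo + 1L):(end[i] - lo + 1L)] <- TRUE
  r <- rle(days)
  # close interior unexposed gaps <= gap_days
  n <- length(r$lengths)
  if (n > 2) {
    for (k in 2:(n - 1)) {
      if (!r$values[k] && r$lengths[k] <= gap_days) r$values[k] <- TRUE
    }
  }
  days <- inverse.rle(r)
  r2 <- rle(days)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  keep <- r2$values & r2$lengths >= min_days
  tibble::tibble(start_day = as.integer(lo + starts[keep] - 1L),
                 end_day = as.integer(lo + ends[keep] - 1L))
}

# Random exposure set for one person and class
random_exposures <- function(n_max = 20L, day_max = 400L) {
  n <- sample.int(n_max, 1)
  s <- sample.int(day_max, n, replace = TRUE)
  d <- sample.int(40L, n, replace = TRUE)
  tibble::tibble(start_day = as.integer(s), end_day = as.integer(s + d - 1L))
}

# Day-level class sets implied by an era table (one person)
oracle_day_sets <- function(eras) {
  if (nrow(eras) == 0) return(list())
  out <- list()
  for (i in seq_len(nrow(eras))) {
    for (d in eras$start_day[i]:eras$end_day[i]) {
      key <- as.character(d)
      out[[key]] <- sort(unique(c(out[[key]], eras$drug_class[i])))
    }
  }
  out
}

# Day-level class sets implied by resolved events (one person)
event_day_sets <- function(events) {
  if (nrow(events) == 0) return(list())
  out <- list()
  for (i in seq_len(nrow(events))) {
    for (d in events$start_day[i]:events$end_day[i]) {
      out[[as.character(d)]] <- sort(unlist(events$classes[i]))
    }
  }
  out
}

# Brute-force prefix counts over a trajectory multiset (list of label vectors)
oracle_prefix_counts <- function(seqs) {
  counts <- list()
  for (s in seqs) {
    for (k in seq_along(s)) {
      key <- paste(s[1:k], collapse = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten a sunburst tree into prefix -> count
sunburst_prefix_counts <- function(tree) {
  out <- list()
  walk <- function(nodes, prefix) {
    for (n in nodes) {
      key <- paste(c(prefix, n$label), collapse = "|")
      out[[key]] <<- n$patient_count
      walk(n$children, c(prefix, n$label))
    }
  }
  walk(tree$children, character(0))
  out
}
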