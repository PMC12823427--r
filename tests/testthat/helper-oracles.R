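## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## Grid-search oracle for the Miettinen-Nurminen score interval: scan delta
## over [-1, 1] at step 1e-6 for the sign changes of |z(delta)| - z_{.975}.
## The restricted MLE is recomputed here by direct numerical likelihood
## maximization, independent of the package's closed-form cubic.
mn_grid_oracle <- function(x1, n1, x2, n2, alpha = 0.05,
                           step = 1e-6, range = c(-1, 1)) {
  num_rmle <- function(d) {
    f <- function(p2) {
      p1 <- p2 + d
      l1 <- if (x1 == 0) 0 else x1 * log(p1)
      l2 <- if (x2 == 0) 0 else x2 * log(p2)
      l1 + (n1 - x1) * log(1 - p1) + l2 + (n2 - x2) * log(1 - p2)
    }
    lo <- max(0, -d) + 1e-12
    hi <- min(1, 1 - d) - 1e-12
    p2 <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-13)$maximum
    c(p2 + d, p2)
  }
  zfun <- function(d) {
    pt <- num_rmle(d)
    N <- n1 + n2
    v <- (pt[1] * (1 - pt[1]) / n1 + pt[2] * (1 - pt[2]) / n2) * N / (N - 1)
    (x1 / n1 - x2 / n2 - d) / sqrt(v)
  }
  zq <- stats::qnorm(1 - alpha / 2)
  dhat <- x1 / n1 - x2 / n2
  ## coarse bracketing scan, then the fine 1e-6 scan near each bound
  coarse <- seq(range[1] + 1e-4, range[2] - 1e-4, by = 1e-3)
  zc <- vapply(coarse, zfun, numeric(1))
  lo_near <- coarse[max(which(zc > zq))]
  hi_near <- coarse[min(which(zc < -zq))]
  fine_lo <- seq(lo_near - 2e-3, min(lo_near + 2e-3, dhat), by = step)
  zl <- vapply(fine_lo, zfun, numeric(1))
  lower <- fine_lo[max(which(zl > zq))]
  fine_hi <- seq(max(hi_near - 2e-3, dhat), hi_near + 2e-3, by = step)
  zh <- vapply(fine_hi, zfun, numeric(1))
  upper <- fine_hi[min(which(zh < -zq))]
  c(lower = 100 * lower, upper = 100 * upper)
}

## Brute-force set-comprehension oracle for the APOBEC-context filter.
## Evidence and membership recomputed from first principles.
filter_oracle <- function(calls, residues, gene, lists) {
  ## expand residue string into position sets (re-implemented)
  sets <- list()
  chars <- strsplit(residues, "")[[1]]
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1
      grp <- character(0)
      while (chars[j] != "]") {
        grp <- c(grp, chars[j])
        j <- j + 1
      }
      sets[[length(sets) + 1]] <- grp
      i <- j + 1
    } else {
      sets[[length(sets) + 1]] <- chars[i]
      i <- i + 1
    }
  }
  sig <- lists$signatures[lists$signatures$gene == gene, ]
  has_sig <- any(vapply(seq_len(nrow(sig)), function(k) {
    p <- sig$position[k]
    p <= length(sets) && sig$aa[k] %in% sets[[p]]
  }, logical(1)))
  has_stop <- any(vapply(sets, function(s) "*" %in% s, logical(1)))
  evidence <- has_sig || has_stop
  ctx <- lists$context[lists$context$gene == gene, ]
  ctx_keys <- paste(ctx$position, ctx$aa)
  dropped <- vapply(calls, function(call) {
    evidence && any(paste(call$position, call$observed_aas) %in% ctx_keys)
  }, logical(1))
  list(retained = calls[!dropped], disregarded = calls[dropped])
}

## construct an in-memory mutation_lists object from data frames
make_lists <- function(drm = NULL, context = NULL, signatures = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    df$position <- integer(0)
    df[cols]
  }
  structure(
    list(
      drm = drm %||% empty(c("gene", "position", "aa", "drug")),
      context = context %||% empty(c("gene", "position", "aa")),
      signatures = signatures %||% empty(c("gene", "position", "aa")),
      stop_codon_symbol = "*"
    ),
    class = "mutation_lists"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## minimal dataset builders used across files
mini_participants <- function(n = 2, arm = rep(c("long_acting", "oral"),
                                               length.out = n)) {
  data.frame(
    participant_id = sprintf("T%03d", seq_len(n)), arm = arm,
    stratum = rep("INSTI", n), randomization_day = rep(0L, n),
    withdrawal_day = rep(NA_integer_, n), death_day = rep(NA_integer_, n),
    oral_lead_in = rep(FALSE, n), sex = rep("female", n),
    baseline_bmi = rep(24, n),
    adjudicated_failure_day = rep(NA_integer_, n),
    adjudication_note = rep(NA_character_, n), stringsAsFactors = FALSE
  )
}

empty_vl <- function() virosnap:::empty_table("viral_loads")
empty_changes <- function() virosnap:::empty_table("regimen_changes")

## small synthetic reference lists: RT signature 20K, IN signature 30N;
## context set {RT 138K, RT 230I, IN 118R}
test_lists <- function() {
  make_lists(
    drm = data.frame(
      gene = c("RT", "RT", "RT", "IN"),
      position = c(138L, 230L, 103L, 118L),
      aa = c("K", "I", "N", "R"),
      drug = c("rilpivirine", "rilpivirine", "efavirenz", "cabotegravir"),
      stringsAsFactors = FALSE),
    context = data.frame(gene = c("RT", "RT", "IN"),
                         position = c(138L, 230L, 118L),
                         aa = c("K", "I", "R"), stringsAsFactors = FALSE),
    signatures = data.frame(gene = c("RT", "IN"), position = c(20L, 30L),
                            aa = c("K", "N"), stringsAsFactors = FALSE)
  )
}

wt_seq <- function(len = 40) paste(rep("A", len), collapse = "")
with_char <- function(s, pos, ch) {
  v <- strsplit(s, "")[[1]]
  v[pos] <- ch
  paste(v, collapse = "")
}

vl_row <- function(pid, day, copies = 0L, lloq = TRUE, week = round(day / 7)) {
  data.frame(participant_id = pid, study_day = as.integer(day),
             nominal_week = as.integer(week),
             copies_per_ml = as.integer(copies), below_lloq = lloq,
             stringsAsFactors = FALSE)
}
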