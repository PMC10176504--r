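# Two-state hidden Markov model over windowed majority k-mer symbols.
#
# The observed symbol of a window is the most common diagnostic k-mer
# type (a or b); the hidden state is the window's true subgenome of
# origin. Homoeologous exchange shows up as maximal runs of windows whose
# decoded state differs from the scaffold's assigned subgenome.

#' Construct the exchange HMM
#'
#' @param switch_prob probability of switching state between adjacent
#'   windows (stays are `1 - switch_prob`).
#' @param start_probs starting probabilities for states A and B.
#' @param emission 2x2 matrix, rows states (A, B), columns symbols
#'   (a, b); rows must sum to 1.
#' @return list of class `hmm_model`.
#' @export
hmm_model <- function(switch_prob = 0.01, start_probs = c(A = 0.5, B = 0.5),
                      emission = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                                        byrow = TRUE,
                                        dimnames = list(c("A", "B"),
                                                        c("a", "b")))) {
  stopifnot(switch_prob > 0, switch_prob < 1,
            length(start_probs) == 2, all(start_probs >= 0),
            abs(sum(start_probs) - 1) < 1e-9,
            all(dim(emission) == c(2, 2)), all(emission >= 0),
            all(abs(rowSums(emission) - 1) < 1e-9))
  dimnames(emission) <- list(c("A", "B"), c("a", "b"))
  structure(list(states = c("A", "B"),
                 start_probs = setNames(as.numeric(start_probs), c("A", "B")),
                 transition = matrix(c(1 - switch_prob, switch_prob,
                                       switch_prob, 1 - switch_prob), 2, 2,
                                     byrow = TRUE,
                                     dimnames = list(c("A", "B"),
                                                     c("A", "B"))),
                 emission = emission), class = "hmm_model")
}

#' Majority symbol per window of a density track
#'
#' `a` if A-preferred hits outnumber B-preferred hits, `b` for the
#' converse, `missing` on ties (including both zero). Windows whose
#' combined hit count falls below `min_hits` are also `missing`: a few
#' scattered hits are indistinguishable from the chance-match background
#' (roughly `|sets| * window / 4^k` per window), and low-signal windows
#' are a known source of misassignment.
#'
#' @param track a [density_track()] data.frame.
#' @param min_hits noise floor on `a_count + b_count` below which a
#'   window carries no evidence.
#' @return character vector of symbols in `{a, b, missing}`.
#' @export
majority_symbols <- function(track, min_hits = 0) {
  ifelse(track$a_count + track$b_count < min_hits, "missing",
         ifelse(track$a_count > track$b_count, "a",
                ifelse(track$b_count > track$a_count, "b", "missing")))
}

#' Viterbi decoding of a symbol sequence
#'
#' Maximum-probability state path in log space. `missing` symbols
#' contribute an emission factor of 1 (no evidence; the transition chain
#' is kept). Ties are broken toward staying in the previous state, which
#' favours fewer segments.
#'
#' @param model an [hmm_model()].
#' @param symbols character vector over `{a, b, missing}`.
#' @return list with `path` (character vector of states) and `logprob`.
#' @export
viterbi <- function(model, symbols) {
  stopifnot(inherits(model, "hmm_model"), length(symbols) > 0,
            all(symbols %in% c("a", "b", "missing")))
  n <- length(symbols)
  lstart <- log(model$start_probs)
  ltrans <- log(model$transition)
  lemit <- log(model$emission)
  emit_at <- function(t) {
    if (symbols[t] == "missing") c(A = 0, B = 0) else lemit[, symbols[t]]
  }
  if (all(symbols == "missing")) {
    warning("all-missing symbol sequence; path is the prior argmax")
    s <- names(which.max(model$start_probs))
    return(list(path = rep(s, n), logprob = max(lstart)))
  }
  delta <- matrix(-Inf, n, 2, dimnames = list(NULL, c("A", "B")))
  back <- matrix(1L, n, 2)
  delta[1, ] <- lstart + emit_at(1)
  for (t in seq_len(n)[-1]) {
    e <- emit_at(t)
    for (s in 1:2) {
      cand <- delta[t - 1, ] + ltrans[, s]
      # sticky tie-break: prefer the predecessor equal to s
      best <- which.max(cand)
      if (cand[s] >= cand[best]) best <- s
      back[t, s] <- best
      delta[t, s] <- cand[best] + e[s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in rev(seq_len(n - 1))) path[t] <- back[t + 1, path[t + 1]]
  list(path = c("A", "B")[path], logprob = max(delta[n, ]))
}

#' Viterbi training of the emission probabilities
#'
#' Iterates decode / re-estimate: symbols are decoded with the current
#' model, emission frequencies are re-estimated per decoded state with
#' Laplace (+1) smoothing over non-missing symbols, and iteration stops
#' when the largest parameter change falls below `tol` or after
#' `max_iter` rounds. Start and transition probabilities are frozen; only
#' the emissions are trained. A state never visited in decoding keeps its
#' emissions, with a warning.
#'
#' @param model an [hmm_model()].
#' @param training_obs list of symbol vectors from scaffolds believed
#'   exchange-free.
#' @param max_iter,tol stopping rule.
#' @return the trained `hmm_model`, with an `iterations` attribute.
#' @export
viterbi_train <- function(model, training_obs, max_iter = 100, tol = 1e-4) {
  stopifnot(length(training_obs) >= 1)
  m <- model
  for (it in seq_len(max_iter)) {
    tab <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("a", "b")))
    for (obs in training_obs) {
      path <- viterbi(m, obs)$path
      keep <- obs != "missing"
      if (any(keep)) {
        t2 <- table(factor(path[keep], c("A", "B")),
                    factor(obs[keep], c("a", "b")))
        tab <- tab + as.matrix(t2)
      }
    }
    new_emit <- m$emission
    unvisited <- rowSums(tab) == 0
    if (any(unvisited)) {
      warning("state never visited in decoding: ",
              paste(c("A", "B")[unvisited], collapse = ", "),
              "; its emissions left unchanged")
    }
    for (s in which(!unvisited)) {
      new_emit[s, ] <- (tab[s, ] + 1) / (sum(tab[s, ]) + 2)
    }
    delta <- max(abs(new_emit - m$emission))
    m$emission <- new_emit
    if (delta < tol) {
      attr(m, "iterations") <- it
      return(m)
    }
  }
  attr(m, "iterations") <- max_iter
  m
}

#' Call exchange segments on one decoded scaffold
#'
#' Maximal runs of windows whose decoded state differs from the assigned
#' subgenome become exchange segments at window resolution. Runs whose
#' windows are all `missing` are not called (no evidence).
#'
#' @param scaffold scaffold name.
#' @param assigned the scaffold's assigned subgenome (`"A"`/`"B"`).
#' @param path decoded state path.
#' @param symbols the observed symbols.
#' @param starts,ends window coordinates (same length as `path`).
#' @return a [feature_table()] of `exchange_segment` features (possibly
#'   empty).
#' @export
call_exchanges <- function(scaffold, assigned, path, symbols, starts, ends) {
  stopifnot(length(path) == length(symbols),
            length(path) == length(starts), length(path) == length(ends))
  diff <- path != assigned
  if (!any(diff)) {
    return(feature_table(character(0), numeric(0), numeric(0),
                         character(0), character(0), character(0)))
  }
  r <- rle(diff)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  seg_start <- idx_start[r$values]
  seg_end <- idx_end[r$values]
  has_evidence <- vapply(seq_along(seg_start), function(i)
    any(symbols[seg_start[i]:seg_end[i]] != "missing"), logical(1))
  seg_start <- seg_start[has_evidence]
  seg_end <- seg_end[has_evidence]
  if (length(seg_start) == 0) {
    return(feature_table(character(0), numeric(0), numeric(0),
                         character(0), character(0), character(0)))
  }
  feature_table(scaffold, starts[seg_start], ends[seg_end], ".",
                "exchange_segment",
                sprintf("%s_exchange_%d", scaffold, seq_along(seg_start)))
}

#' Detect homoeologous exchange across all scaffolds
#'
#' Convenience driver: builds majority symbols from each scaffold's
#' density track, optionally trains emissions on user-chosen
#' exchange-free scaffolds, decodes every scaffold with Viterbi, and
#' calls segments where the decoded state disagrees with the assignment.
#'
#' @param assignment a [cluster_subgenomes()] result.
#' @param tracks named list of [density_track()] data.frames.
#' @param model an [hmm_model()].
#' @param min_hits noise floor passed to [majority_symbols()]; the
#'   default of 25 sits a few-fold above the chance-match background of
#'   the diagnostic sets at both desk and chromosome scale.
#' @param train_scaffolds scaffold names used for Viterbi training of the
#'   emissions; `"auto"` (default) picks the cleanest scaffold of each
#'   subgenome (lowest fraction of minority symbols, the programmatic
#'   version of choosing visually exchange-free training scaffolds);
#'   `NULL` keeps the model as given.
#' @return list with `calls` (combined [feature_table()]), `paths`,
#'   `symbols`, `train_scaffolds` and the final `model`.
#' @export
detect_exchanges <- function(assignment, tracks, model = hmm_model(),
                             min_hits = 25, train_scaffolds = "auto") {
  stopifnot(inherits(assignment, "subgenome_assignment"))
  asg <- assignment$assignment
  stopifnot(all(names(tracks) %in% names(asg)))
  symbols <- lapply(tracks, majority_symbols, min_hits = min_hits)
  if (identical(train_scaffolds, "auto")) {
    minority <- vapply(names(tracks), function(s) {
      sym <- symbols[[s]]
      expected <- tolower(asg[[s]])
      informative <- sym != "missing"
      if (!any(informative)) return(1)
      mean(sym[informative] != expected)
    }, numeric(1))
    train_scaffolds <- vapply(c("A", "B"), function(side) {
      cand <- names(tracks)[asg[names(tracks)] == side]
      cand[which.min(minority[cand])]
    }, character(1))
  }
  if (!is.null(train_scaffolds)) {
    stopifnot(all(train_scaffolds %in% names(tracks)))
    model <- viterbi_train(model, symbols[train_scaffolds])
  }
  paths <- lapply(symbols, function(s) viterbi(model, s)$path)
  calls <- lapply(names(tracks), function(s) {
    call_exchanges(s, asg[[s]], paths[[s]], symbols[[s]],
                   tracks[[s]]$start, tracks[[s]]$end)
  })
  calls <- do.call(rbind, calls)
  class(calls) <- c("feature_table", "data.frame")
  list(calls = calls, paths = paths, symbols = symbols,
       train_scaffolds = train_scaffolds, model = model)
}
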