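# Construction of balanced presentation lists for the listening
# experiment: 32 stimuli per list (4 pairs x 8 segments), 8 per
# manipulation scheme, 2 per pair x scheme, randomized order, with
# distinct draw seeds across lists.

#' Build a segment inventory
#'
#' Convenience constructor for the 32-segment inventory (4 conversation
#' pairs, 8 segments each). Durations and transfer counts default to
#' draws emulating the study conditions: segment lengths 29.0-36.9 s and
#' 12-25 floor transfers.
#'
#' @param n_pairs number of conversation pairs (4).
#' @param segments_per_pair segments per pair (8).
#' @param seed integer seed for the emulated durations/counts.
#' @return data frame with `pair_id`, `segment_idx`, `duration_s`,
#'   `n_transfers`.
#' @export
segment_inventory <- function(n_pairs = 4, segments_per_pair = 8,
                              seed = NULL) {
  with_seed(seed, {
    n <- n_pairs * segments_per_pair
    data.frame(pair_id = rep(seq_len(n_pairs), each = segments_per_pair),
               segment_idx = rep(seq_len(segments_per_pair), n_pairs),
               duration_s = round(stats::runif(n, 29.0, 36.9), 1),
               n_transfers = sample(12:25, n, replace = TRUE))
  })
}

#' Build balanced presentation lists
#'
#' Generates `n_lists` lists over a 32-segment inventory. Every list uses
#' every segment exactly once, assigns each manipulation scheme to 8
#' stimuli -- exactly 2 randomly chosen segments per (pair, scheme) -- and
#' randomizes presentation order. NHQ/HIN draw seeds are derived per
#' (list, pair, segment), so different lists apply different random FTO
#' values (8 NHQ slots x 10 lists = 80 distinct renderings by default).
#'
#' @param segments segment inventory data frame (`pair_id`,
#'   `segment_idx`, plus optional metadata columns); must contain exactly
#'   4 pairs x 8 segments.
#' @param n_lists number of lists (default 10).
#' @param master_seed integer master seed; everything is reproducible
#'   from it.
#' @return list of `presentation_list` objects: `list_id`, `assignments`
#'   (data frame with `trial`, `pair_id`, `segment_idx`, `scheme`,
#'   `seed`).
#' @export
build_lists <- function(segments, n_lists = 10, master_seed = 1) {
  stopifnot(is.data.frame(segments),
            all(c("pair_id", "segment_idx") %in% names(segments)))
  pairs <- sort(unique(segments$pair_id))
  if (length(pairs) != 4)
    stop("segment inventory must contain exactly 4 pairs")
  for (p in pairs)
    if (sum(segments$pair_id == p) != 8)
      stop("each pair must contribute exactly 8 segments")
  schemes <- c("conLow", "conNHQ", "NHQ", "HIN")

  lapply(seq_len(n_lists), function(l) {
    rows <- list()
    for (p in pairs) {
      seg <- segments[segments$pair_id == p, , drop = FALSE]
      perm <- with_seed(derive_seed(master_seed, "assign", l, p),
                       sample(nrow(seg)))
      seg <- seg[perm, , drop = FALSE]
      seg$scheme <- rep(schemes, each = 2)
      rows[[length(rows) + 1]] <- seg
    }
    a <- do.call(rbind, rows)
    a$seed <- mapply(function(p, s) derive_seed(master_seed, "draw", l, p, s),
                     a$pair_id, a$segment_idx)
    ord <- with_seed(derive_seed(master_seed, "order", l), sample(nrow(a)))
    a <- a[ord, , drop = FALSE]
    a$trial <- seq_len(nrow(a))
    rownames(a) <- NULL
    structure(list(list_id = l,
                   assignments = a[, c("trial", "pair_id", "segment_idx",
                                       "scheme", "seed",
                                       setdiff(names(a),
                                               c("trial", "pair_id",
                                                 "segment_idx", "scheme",
                                                 "seed")))]),
              class = "presentation_list")
  })
}

#' @export
print.presentation_list <- function(x, ...) {
  cat(sprintf("<presentation_list %d: %d trials, schemes %s>\n", x$list_id,
              nrow(x$assignments),
              paste(names(table(x$assignments$scheme)), collapse = "/")))
  invisible(x)
}

#' Static description of the listening-experiment protocol
#'
#' The three rated attributes with their on-screen questions and
#' visual-analogue-scale anchor labels, the scale coding convention, and
#' the break schedule (a self-paced break after every eighth stimulus).
#'
#' @return list with `attributes` (data frame), `vas_range`,
#'   `break_after`, `n_trials`.
#' @export
describe_protocol <- function() {
  attrs <- data.frame(
    attribute = c("naturalness", "flow", "ease_of_following"),
    question = c("How natural did you find the conversation?",
                 "How free-flowing did you find the conversation?",
                 "How easy was it for you to follow the conversation?"),
    anchor_low = c("Completely natural", "Not at all free-flowing",
                   "Very difficult"),
    anchor_high = c("Completely unnatural", "Completely free-flowing",
                    "Very easy"),
    anchor_mid = "neither/nor")
  list(attributes = attrs, vas_range = c(1, 5),
       break_after = c(8, 16, 24), n_trials = 32)
}

#' Serialize presentation lists to a flat data frame
#'
#' @param lists output of [build_lists()].
#' @return data frame with one row per (list, trial).
#' @export
lists_to_df <- function(lists) {
  out <- do.call(rbind, lapply(lists, function(pl) {
    a <- pl$assignments
    a$list_id <- pl$list_id
    a
  }))
  rownames(out) <- NULL
  out
}
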