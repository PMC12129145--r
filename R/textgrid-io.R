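# Praat TextGrid interval-tier serialization for VAD masks and timelines.

#' Write interval tiers to a Praat TextGrid file
#'
#' @param tiers named list of data frames, each with columns `start`, `end`
#'   and `label` (seconds; gaps are filled with empty-label intervals).
#' @param path output path.
#' @param xmin,xmax tier bounds in seconds; `xmax` defaults to the largest
#'   interval end.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tiers, path, xmin = 0, xmax = NULL) {
  stopifnot(is.list(tiers), length(tiers) >= 1, !is.null(names(tiers)))
  if (is.null(xmax))
    xmax <- max(vapply(tiers, function(d) if (nrow(d)) max(d$end) else 0,
                       numeric(1)))
  num <- function(x) format(x, nsmall = 6, trim = TRUE, scientific = FALSE)
  out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
           paste0("xmin = ", num(xmin)), paste0("xmax = ", num(xmax)),
           "tiers? <exists>", paste0("size = ", length(tiers)), "item []:")
  for (i in seq_along(tiers)) {
    d <- tiers[[i]]
    full <- fill_tier_gaps(d, xmin, xmax)
    out <- c(out,
             paste0("    item [", i, "]:"),
             '        class = "IntervalTier"',
             paste0('        name = "', names(tiers)[i], '"'),
             paste0("        xmin = ", num(xmin)),
             paste0("        xmax = ", num(xmax)),
             paste0("        intervals: size = ", nrow(full)))
    for (j in seq_len(nrow(full))) {
      out <- c(out,
               paste0("        intervals [", j, "]:"),
               paste0("            xmin = ", num(full$start[j])),
               paste0("            xmax = ", num(full$end[j])),
               paste0('            text = "', full$label[j], '"'))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# insert empty-label intervals so the tier tiles [xmin, xmax]
fill_tier_gaps <- function(d, xmin, xmax) {
  if (is.null(d) || nrow(d) == 0)
    return(data.frame(start = xmin, end = xmax, label = ""))
  d <- d[order(d$start), , drop = FALSE]
  rows <- list()
  cur <- xmin
  for (j in seq_len(nrow(d))) {
    if (d$start[j] > cur + 1e-9)
      rows[[length(rows) + 1]] <- data.frame(start = cur, end = d$start[j],
                                             label = "")
    rows[[length(rows) + 1]] <- d[j, c("start", "end", "label")]
    cur <- d$end[j]
  }
  if (cur < xmax - 1e-9)
    rows[[length(rows) + 1]] <- data.frame(start = cur, end = xmax,
                                           label = "")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read interval tiers from a Praat TextGrid file
#'
#' Parses the long ("text") TextGrid format written by [write_textgrid()]
#' and by Praat itself.
#'
#' @param path path to a `.TextGrid` file.
#' @return named list of data frames with columns `start`, `end`, `label`.
#' @export
read_textgrid <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  grab <- function(line, key) {
    m <- regmatches(line, regexec(paste0("^", key, " = (.*)$"), line))[[1]]
    if (length(m) < 2) NULL else m[2]
  }
  tiers <- list()
  tier_name <- NULL
  cur <- NULL   # data.frame rows for the tier in progress
  pend <- list()
  flush_tier <- function() {
    if (!is.null(tier_name)) {
      d <- if (length(pend)) do.call(rbind, pend) else
        data.frame(start = numeric(0), end = numeric(0),
                   label = character(0))
      rownames(d) <- NULL
      tiers[[tier_name]] <<- d
    }
    pend <<- list()
  }
  i <- 1
  xmin <- NA_real_
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!is.null(v <- grab(ln, "name"))) {
      flush_tier()
      tier_name <- gsub('^"|"$', "", v)
    } else if (grepl("^intervals \\[", ln)) {
      x0 <- as.numeric(grab(lines[i + 1], "xmin"))
      x1 <- as.numeric(grab(lines[i + 2], "xmax"))
      lab <- gsub('^"|"$', "", grab(lines[i + 3], "text"))
      pend[[length(pend) + 1]] <- data.frame(start = x0, end = x1,
                                             label = lab)
      i <- i + 3
    }
    i <- i + 1
  }
  flush_tier()
  tiers
}
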