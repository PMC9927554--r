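RM_HEADER <- c(
  "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
  "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)     ID",
  "")

#' Parse a RepeatMasker .out annotation file
#'
#' The standard layout: 3 header lines, then whitespace-separated rows.
#' Parenthesized fields (bases left to the end) are parsed as negative values.
#' For strand `C` (reverse) the repeat-coordinate columns appear as
#' (left), end, begin and are normalized so that `consensus_begin` <
#' `consensus_end` always holds.  [write_rm_out()] inverts the convention,
#' so `write(parse(f))` reproduces `f` modulo whitespace.
#'
#' @param path .out file path
#' @return data.frame with columns sw_score, pct_div, pct_del, pct_ins,
#'   query_name, query_begin, query_end (1-based inclusive), query_left,
#'   strand (+/C), repeat_name, repeat_class, consensus_begin, consensus_end,
#'   consensus_left, annot_id
#' @export
parse_rm_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) >= 3) lines <- lines[-(1:3)]
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(sw_score = integer(0), pct_div = numeric(0),
                      pct_del = numeric(0), pct_ins = numeric(0),
                      query_name = character(0), query_begin = integer(0),
                      query_end = integer(0), query_left = integer(0),
                      strand = character(0), repeat_name = character(0),
                      repeat_class = character(0),
                      consensus_begin = integer(0),
                      consensus_end = integer(0), consensus_left = integer(0),
                      annot_id = integer(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  paren <- function(x, lineno) {
    v <- suppressWarnings(as.numeric(gsub("[()]", "", x)))
    if (is.na(v)) stop("malformed numeric field '", x, "' at line ", lineno)
    if (grepl("^\\(", x)) -v else v
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    lineno <- i + 3
    if (length(f) < 15)
      stop("malformed row (", length(f), " fields, need >= 15) at line ",
           lineno)
    strand <- f[9]
    if (!strand %in% c("+", "C"))
      stop("unknown strand symbol '", strand, "' at line ", lineno)
    r <- lapply(f[c(12, 13, 14)], paren, lineno = lineno)
    if (strand == "+") {
      cb <- r[[1]]; ce <- r[[2]]; cl <- r[[3]]
    } else {
      cl <- r[[1]]; ce <- r[[2]]; cb <- r[[3]]
    }
    data.frame(sw_score = as.integer(f[1]), pct_div = as.numeric(f[2]),
               pct_del = as.numeric(f[3]), pct_ins = as.numeric(f[4]),
               query_name = f[5],
               query_begin = as.integer(f[6]), query_end = as.integer(f[7]),
               query_left = as.integer(paren(f[8], lineno)),
               strand = strand, repeat_name = f[10], repeat_class = f[11],
               consensus_begin = as.integer(cb), consensus_end = as.integer(ce),
               consensus_left = as.integer(cl),
               annot_id = as.integer(f[15]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$query_begin > out$query_end))
    stop("query_begin > query_end at line ",
         which(out$query_begin > out$query_end)[1] + 3)
  out
}

#' Write RepeatMasker .out annotations
#' @param annotations a data.frame as returned by [parse_rm_out()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rm_out <- function(annotations, path) {
  a <- annotations
  left_fmt <- function(x) paste0("(", -x, ")")   # "left" fields: always parens
  body <- vapply(seq_len(nrow(a)), function(i) {
    r12 <- if (a$strand[i] == "+") as.character(a$consensus_begin[i])
           else left_fmt(a$consensus_left[i])
    r14 <- if (a$strand[i] == "+") left_fmt(a$consensus_left[i])
           else as.character(a$consensus_begin[i])
    sprintf("%6d %5.1f %5.1f %5.1f  %-10s %8d %8d %9s %s %-15s %-20s %6s %5d %6s %6d",
            a$sw_score[i], a$pct_div[i], a$pct_del[i], a$pct_ins[i],
            a$query_name[i], a$query_begin[i], a$query_end[i],
            left_fmt(a$query_left[i]), a$strand[i], a$repeat_name[i],
            a$repeat_class[i], r12, a$consensus_end[i],
            r14, a$annot_id[i])
  }, "")
  con <- file(path, "wb")
  writeLines(c(RM_HEADER, body), con, sep = "\n")
  close(con)
  invisible(path)
}
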