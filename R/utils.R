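`%||%` <- function(x, y) if (is.null(x)) y else x

# "YYYY-MM" label of a Date (calendar-month bucketing for transmission logs)
month_label <- function(date) format(date, "%Y-%m")

# Sequence of "YYYY-MM" labels from the month of `from` to the month of `to`
month_seq <- function(from, to) {
  from <- as.Date(paste0(month_label(as.Date(from)), "-01"))
  to <- as.Date(paste0(month_label(as.Date(to)), "-01"))
  if (to < from) stop("month horizon is empty", call. = FALSE)
  month_label(seq(from, to, by = "month"))
}
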