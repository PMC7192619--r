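## Internal helpers shared across modules.

stop_axonedit <- function(..., class) {
  stop(structure(
    class = c(class, "axonedit_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

abort_parse <- function(...) stop_axonedit(..., class = "axonedit_parse_error")
abort_validation <- function(...) stop_axonedit(..., class = "axonedit_validation_error")

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & x == floor(x)
}

is_fraction <- function(x, open = FALSE) {
  if (open) is.numeric(x) && !is.na(x) && x > 0 && x < 1
  else is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

site_key <- function(transcript_id, position) {
  paste(transcript_id, position, sep = "\r")
}
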