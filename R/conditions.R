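# Structured error conditions. Every user-facing failure mode has a stable
# condition class ("kx_" + kebab-case name with "-" -> "_") so callers can
# dispatch on it with tryCatch()/expect_error(class = ...).

kx_stop <- function(class, message, data = list(), call. = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("kx_", gsub("-", "_", class, fixed = TRUE)),
              "kx_error", "error", "condition"),
    list(message = message, call = call., data = data)
  )
  stop(cond)
}

kx_warn <- function(class, message, data = list()) {
  cond <- structure(
    class = c(paste0("kx_", gsub("-", "_", class, fixed = TRUE)),
              "kx_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  warning(cond)
}

#' @export
print.kx_error <- function(x, ...) {
  cat("<", class(x)[1], "> ", conditionMessage(x), "\n", sep = "")
  invisible(x)
}
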