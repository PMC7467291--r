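# internal helpers

logit <- function(p) log(p) - log1p(-p)

inv_logit <- function(x) stats::plogis(x)

# named-list / named-vector parameter access with a clear error
pval <- function(params, name) {
  v <- params[[name]]
  if (is.null(v) || is.na(v)) {
    stop("parameter `", name, "` missing from parameter set", call. = FALSE)
  }
  v
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single non-missing number", call. = FALSE)
  }
  invisible(x)
}
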