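# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# relative tolerance used when deciding whether a threshold region is empty
.region_tol <- 1e-9

# lightweight logging: messages routed through one function so the CLI can
# silence or redirect them
occ_log <- function(..., verbose = getOption("suborders.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[suborders] ", ...)
  invisible(NULL)
}

stop2 <- function(...) stop(..., call. = FALSE)

# canonical string key for a label sequence
seq_key <- function(x) paste(x, collapse = "\r")

key_seq <- function(k) strsplit(k, "\r", fixed = TRUE)[[1]]
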