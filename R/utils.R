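#' @keywords internal
"_PACKAGE"

## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 1 && x == floor(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## FNV-1a over the deparsed object; used only for provenance headers
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    ## xor the low byte (h may exceed the 32-bit signed range of bitwXor)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    ## 32-bit modular multiply via 16-bit split to stay within double
    ## precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

## linear predictor from a named coefficient vector over columns of `data`
.lp <- function(coefs, data) {
  if (is.null(coefs) || length(coefs) == 0L) {
    return(rep(0, nrow(data)))
  }
  missing_cols <- setdiff(names(coefs), names(data))
  if (length(missing_cols)) {
    .stopf("covariate effect refers to unknown column(s): %s",
           paste(missing_cols, collapse = ", "))
  }
  out <- rep(0, nrow(data))
  for (nm in names(coefs)) out <- out + coefs[[nm]] * data[[nm]]
  out
}
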