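# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data.frame as CSV with round-trip numeric precision (17 significant
# digits survive double -> text -> double exactly), NA as empty cell.
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- out[[j]]
      s <- vapply(x, function(v) {
        if (is.na(v)) "" else {
          # shortest representation that round-trips
          for (d in c(15L, 16L, 17L)) {
            r <- sprintf("%.*g", d, v)
            if (as.numeric(r) == v) return(r)
          }
          r
        }
      }, character(1))
      out[[j]] <- s
    } else if (is.logical(out[[j]]) || is.integer(out[[j]])) {
      s <- as.character(as.integer(out[[j]]))
      s[is.na(s)] <- ""
      out[[j]] <- s
    } else {
      s <- as.character(out[[j]])
      s[is.na(s)] <- ""
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  check.names = FALSE)
}

is_binary01 <- function(x) all(is.na(x) | x %in% c(0, 1))

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# standardization helpers ----------------------------------------------------

# (x - mu) / sigma  -- exposures (per 1 SD of ln concentration)
std1 <- function(x, mu, sigma) (x - mu) / sigma

# (x - mu) / (2 sigma) -- continuous covariates (per 2 SD change)
std2 <- function(x, mu, sigma) (x - mu) / (2 * sigma)
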