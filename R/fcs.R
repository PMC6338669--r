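# Minimal FCS 3.0/3.1 list-mode I/O.
#
# Reads the HEADER and TEXT segments, then the DATA segment for list-mode
# ($MODE L) files with $DATATYPE F (float32), D (float64) or I (unsigned
# integer, $PnB in {8,16,32}).  Both byte orders are supported.  Spillover/
# compensation keywords are ignored.  The writer emits FCS 3.1 float32
# little-endian files, which the reader round-trips to float precision.

#' Read an FCS 3.0/3.1 file
#'
#' @param path file path.
#' @return A list with \code{data} (event-by-parameter numeric matrix,
#'   columns named by \code{$PnN}) and \code{keywords} (named character
#'   vector of the TEXT segment).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("format error: unsupported FCS version '", version, "'",
         call. = FALSE)
  off <- function(i) {
    s <- substr(header, 10 + (i - 1) * 8 + 1, 10 + i * 8)
    as.integer(trimws(s))
  }
  text_start <- off(1); text_end <- off(2)
  seek(con, text_start)
  txt <- rawToChar(readBin(con, "raw", text_end - text_start + 1L))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1L) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 toupper(trimws(parts[seq(1, length(parts), 2)])))
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  data_start <- as.integer(kw[["$BEGINDATA"]] %||% off(3))
  if (is.na(data_start) || data_start == 0L) data_start <- off(3)
  seek(con, data_start)
  n_val <- n_par * n_tot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n_val, size = 4L, endian = endian),
    D = readBin(con, "numeric", n_val, size = 8L, endian = endian),
    I = {
      bits <- as.integer(kw[["$P1B"]])
      readBin(con, "integer", n_val, size = bits %/% 8L,
              signed = bits < 32L, endian = endian)
    },
    stop("format error: unsupported $DATATYPE '", dtype, "'", call. = FALSE))
  mat <- matrix(as.numeric(vals), ncol = n_par, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(n_par), function(i)
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), "")
  list(data = mat, keywords = kw)
}

#' Write an FCS 3.1 file
#'
#' Emits a minimal valid FCS 3.1 list-mode file: float32 values,
#' little-endian, linear scale (\code{$PnE 0,0}), one parameter per matrix
#' column.
#'
#' @param data numeric matrix, events in rows, parameters in columns
#'   (column names become \code{$PnN}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fcs <- function(data, path) {
  data <- as.matrix(data)
  if (nrow(data) == 0L)
    stop("empty-data error: no events to write", call. = FALSE)
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("P%d", seq_len(ncol(data)))
  n_par <- ncol(data); n_tot <- nrow(data)
  d <- "/"
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par))
    kv <- c(kv,
            sprintf("$P%dN", i), colnames(data)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), sprintf("%d", ceiling(max(data[, i], 1))))
  make_text <- function(bd, ed) {
    vals <- kv
    vals[vals == "%BD%"] <- sprintf("%010d", bd)
    vals[vals == "%ED%"] <- sprintf("%010d", ed)
    paste0(d, paste(vals, collapse = d), d)
  }
  text_start <- 58L
  text_len <- nchar(make_text(0L, 0L))          # widths fixed by %010d
  data_start <- text_start + text_len
  data_end <- data_start + 4L * n_par * n_tot - 1L
  txt <- make_text(data_start, data_end)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + text_len - 1L,
                    data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
  invisible(path)
}
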