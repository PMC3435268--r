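# Minimal EDF/EDF+ signal import. EDF stores an ASCII header followed by
# data records of 16-bit little-endian integers; physical units are
# recovered from the per-signal calibration fields. Only equal-rate signals
# are supported; annotation channels ("EDF Annotations") are dropped.

read_edf_session <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr_num <- function(n) as.numeric(hdr_txt(n))
  hdr_txt(8)                      # version
  hdr_txt(80); hdr_txt(80)        # patient / recording id
  hdr_txt(8); hdr_txt(8)          # start date / time
  hdr_num(8)                      # header bytes
  hdr_txt(44)                     # reserved
  n_rec <- hdr_num(8)
  rec_dur <- hdr_num(8)
  ns <- as.integer(hdr_num(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr_txt(w), character(1))
  labels <- field(16)
  field(80); field(8)             # transducer, unit
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                       # prefiltering
  spr <- as.integer(field(8))     # samples per record per signal
  field(32)                       # reserved
  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("format error: no signal channels in EDF")
  if (length(unique(spr[keep])) != 1)
    stop("format error: EDF signals with mixed sampling rates are unsupported")
  if (n_rec < 0) stop("format error: unknown record count in EDF")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- matrix(0, nrow = sum(keep), ncol = n_rec * spr[keep][1])
  col0 <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      if (keep[s]) {
        row <- sum(keep[seq_len(s)])
        out[row, col0 + seq_len(spr[s])] <- gain[s] * raw + offset[s]
      }
    }
    col0 <- col0 + spr[keep][1]
  }
  recording_session(out, rate = spr[keep][1] / rec_dur,
                    channels = data.frame(id = labels[keep],
                                          region = "unknown",
                                          excluded = FALSE,
                                          stringsAsFactors = FALSE))
}

# Companion writer used to build round-trip fixtures in tests; quantises to
# the EDF 16-bit range, so round trips are exact only for integer-valued
# physical signals within the declared physical range.
write_edf <- function(session, path, phys_range = NULL) {
  m <- session$samples
  if (is.null(phys_range)) phys_range <- range(m) + c(-1, 1)
  ns <- nrow(m)
  rec_dur <- 1
  spr <- as.integer(session$rate * rec_dur)
  n_rec <- as.integer(ceiling(ncol(m) / spr))
  if (n_rec * spr != ncol(m))
    m <- cbind(m, matrix(0, ns, n_rec * spr - ncol(m)))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeBin(charToRaw(paste(substr(s, 1, w), collapse = "")), con)
  }
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(as.character(256 * (ns + 1)), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad(as.character(rec_dur), 8)
  pad(as.character(ns), 4)
  padv <- function(v, w) for (x in v) pad(x, w)
  padv(session$channels$id, 16)
  padv(rep("", ns), 80); padv(rep("uV", ns), 8)
  padv(rep(format(phys_range[1]), ns), 8)
  padv(rep(format(phys_range[2]), ns), 8)
  padv(rep("-32768", ns), 8); padv(rep("32767", ns), 8)
  padv(rep("", ns), 80); padv(rep(as.character(spr), ns), 8)
  padv(rep("", ns), 32)
  gain <- (phys_range[2] - phys_range[1]) / 65535
  for (r in seq_len(n_rec)) {
    cols <- (r - 1) * spr + seq_len(spr)
    for (s in seq_len(ns)) {
      dig <- round((m[s, cols] - phys_range[1]) / gain) - 32768
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
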