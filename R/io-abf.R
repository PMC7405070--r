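# Minimal Axon Binary Format (ABF v1.x) support for episodic current-clamp
# recordings: enough of the fixed 2048-byte ABF1 header to round-trip
# multi-sweep step protocols with a recorded stimulus channel. ABF2 files and
# gap-free/voltage-clamp protocols are rejected.

.abf_hdr_len <- 2048L

abf_rd <- function(raw, offset, what, n = 1L, size = NA) {
  readBin(raw[(offset + 1L):length(raw)], what = what, n = n, size = size,
          endian = "little")
}

abf_rd_str <- function(raw, offset, nchars) {
  b <- raw[(offset + 1L):(offset + nchars)]
  rawToChar(b[b != as.raw(0)])
}

#' Read an episodic current-clamp ABF v1 file
#'
#' Supports ABF version 1.x episodic files, int16 or float32 data. Current
#' amplitudes are recovered from a recorded stimulus channel (units pA) when
#' one is present, otherwise from the epoch table. The first mV channel is
#' taken as the membrane potential.
#'
#' @param path ABF file.
#' @param cell_id Cell identifier; defaults to the file name.
#' @param temperature Bath temperature (degrees Celsius), not stored in ABF1.
#' @return A [sweepset()].
#' @export
read_abf <- function(path, cell_id = NULL, temperature = NA_real_) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < .abf_hdr_len) abort("file too short to be an ABF file")
  sig <- rawToChar(raw[1:4])
  if (sig == "ABF2") abort("ABF2 files are not supported; export as ABF v1 or CSV")
  if (sig != "ABF ") abort("not an ABF file (bad signature)")
  mode <- abf_rd(raw, 8, "integer", size = 2)
  if (mode != 5L) abort("not an episodic (sweep-based) protocol")
  acq_len   <- abf_rd(raw, 10, "integer", size = 4)
  episodes  <- abf_rd(raw, 16, "integer", size = 4)
  data_ptr  <- abf_rd(raw, 40, "integer", size = 4)
  fmt       <- abf_rd(raw, 100, "integer", size = 2)
  nch       <- abf_rd(raw, 120, "integer", size = 2)
  dt_us     <- abf_rd(raw, 122, "double", size = 4)
  per_ep    <- abf_rd(raw, 138, "integer", size = 4)
  adc_range <- abf_rd(raw, 244, "double", size = 4)
  adc_res   <- abf_rd(raw, 252, "integer", size = 4)
  units <- vapply(seq_len(nch) - 1L,
                  function(i) trimws(abf_rd_str(raw, 602 + 8L * i, 8L)),
                  character(1))
  pgain  <- abf_rd(raw, 730, "double", n = 16, size = 4)
  iscale <- abf_rd(raw, 922, "double", n = 16, size = 4)
  ioff   <- abf_rd(raw, 986, "double", n = 16, size = 4)
  sgain  <- abf_rd(raw, 1050, "double", n = 16, size = 4)
  soff   <- abf_rd(raw, 1114, "double", n = 16, size = 4)
  if (episodes < 1L || per_ep < 1L || acq_len != episodes * per_ep)
    abort("inconsistent episode bookkeeping in ABF header")
  if (per_ep %% nch != 0L) abort("mismatched sweep lengths across channels")
  n <- per_ep %/% nch
  rate <- 1e6 / dt_us

  off <- data_ptr * 512L
  if (fmt == 1L) {
    vals <- abf_rd(raw, off, "double", n = acq_len, size = 4)
  } else if (fmt == 0L) {
    ri <- abf_rd(raw, off, "integer", n = acq_len, size = 2)
    vals <- numeric(acq_len)
    for (ch in seq_len(nch)) {
      idx <- seq(ch, acq_len, by = nch)
      vals[idx] <- ri[idx] * (adc_range / adc_res) /
        (pgain[ch] * iscale[ch] * sgain[ch]) + ioff[ch] - soff[ch]
    }
  } else abort("unsupported ABF data format")

  chan <- function(ch, ep) {
    base <- (ep - 1L) * per_ep
    vals[base + seq(ch, per_ep, by = nch)]
  }
  v_ch <- match("mV", units)
  if (is.na(v_ch)) abort("no mV channel: not a current-clamp recording")
  i_ch <- match("pA", units)
  volts <- lapply(seq_len(episodes), function(ep) chan(v_ch, ep))

  if (!is.na(i_ch)) {
    cur <- lapply(seq_len(episodes), function(ep) chan(i_ch, ep))
    base_n <- max(8L, n %/% 20L)
    baselines <- vapply(cur, function(x) stats::median(x[1:base_n]), numeric(1))
    dev <- Reduce(pmax, purrr::map2(cur, baselines, function(x, b) abs(x - b)))
    if (max(dev) > 1e-6) {
      inside <- which(dev > 0.5 * max(dev))
      onset <- (inside[1] - 1L) / rate
      duration <- length(inside) / rate
      amps <- vapply(seq_len(episodes), function(ep)
        stats::median(cur[[ep]][inside]) - baselines[ep], numeric(1))
    } else {
      onset <- 0.1; duration <- min(1.0, n / rate - onset)
      amps <- baselines
    }
  } else {
    etype <- abf_rd(raw, 1436, "integer", n = 8, size = 2)
    if (etype[1] != 1L) abort("missing stimulus information (no pA channel, no step epoch)")
    lvl0 <- abf_rd(raw, 1452, "double", n = 8, size = 4)[1]
    linc <- abf_rd(raw, 1484, "double", n = 8, size = 4)[1]
    edur <- abf_rd(raw, 1516, "integer", n = 8, size = 4)[1]
    amps <- lvl0 + (seq_len(episodes) - 1L) * linc
    onset <- 0.1
    duration <- if (edur > 0) edur / rate else min(1.0, n / rate - onset)
  }
  amps <- round(amps, 3)
  sweepset(volts, amps, rate, stim_onset = onset, stim_duration = duration,
           cell_id = cell_id %||% sub("\\.[^.]*$", "", basename(path)),
           temperature = temperature, check_stimulus = FALSE)
}

#' Write a sweep set as an ABF v1 episodic file
#'
#' Writes a two-channel episodic ABF v1.8 file (channel 0: membrane potential,
#' mV; channel 1: injected current, pA) with float32 samples, readable by
#' [read_abf()] and by standard ABF tooling that accepts version-1 files.
#'
#' @param s A [sweepset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_abf <- function(s, path) {
  n <- length(s$voltages[[1]])
  nep <- length(s$voltages)
  nch <- 2L
  rate <- s$sampling_rate
  stim <- stim_index(s)
  con <- file(path, "wb")
  on.exit(close(con))
  buf <- raw(.abf_hdr_len)
  put <- function(offset, value, size, what = "integer") {
    b <- writeBin(value, raw(), size = size, endian = "little")
    buf[(offset + 1L):(offset + length(b))] <<- b
  }
  put_str <- function(offset, value, width) {
    b <- charToRaw(formatC(value, width = -width))
    buf[(offset + 1L):(offset + width)] <<- b[1:width]
  }
  buf[1:4] <- charToRaw("ABF ")
  put(4, 1.83, 4, "double")              # fFileVersionNumber
  put(8, 5L, 2)                          # nOperationMode: episodic
  put(10, n * nch * nep, 4)              # lActualAcqLength
  put(16, nep, 4)                        # lActualEpisodes
  put(40, .abf_hdr_len %/% 512L, 4)      # lDataSectionPtr (512-byte blocks)
  put(100, 1L, 2)                        # nDataFormat: float32
  put(120, nch, 2)
  put(122, 1e6 / rate, 4, "double")      # fADCSampleInterval (us)
  put(138, n * nch, 4)                   # lNumSamplesPerEpisode
  put(244, 10, 4, "double")              # fADCRange
  put(252, 32768L, 4)                    # lADCResolution
  for (i in 0:15) put(410 + 2L * i, if (i < nch) i else -1L, 2)  # sampling seq
  put_str(602, "mV", 8); put_str(610, "pA", 8)
  for (i in 0:15) {
    put(730 + 4L * i, 1, 4, "double")    # programmable gain
    put(922 + 4L * i, 1, 4, "double")    # instrument scale factor
    put(986 + 4L * i, 0, 4, "double")    # instrument offset
    put(1050 + 4L * i, 1, 4, "double")   # signal gain
    put(1114 + 4L * i, 0, 4, "double")   # signal offset
  }
  put(1436, 1L, 2)                                        # epoch 0: step
  put(1452, s$current_pa[1], 4, "double")                 # init level
  inc <- if (nep > 1) diff(s$current_pa) else 0
  put(1484, if (nep > 1 && all(abs(inc - inc[1]) < 1e-9)) inc[1] else 0,
      4, "double")
  put(1516, length(stim), 4)                              # epoch duration
  writeBin(buf, con)
  for (ep in seq_len(nep)) {
    cur <- numeric(n)
    cur[stim] <- s$current_pa[ep]
    inter <- as.vector(rbind(s$voltages[[ep]], cur))
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}
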