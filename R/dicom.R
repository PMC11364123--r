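# Minimal DICOM codec (explicit VR little endian) for RT Plan and RT Dose.
#
# Only the subset of the standard needed to carry a sliding-window IMRT plan
# (BeamSequence / ControlPointSequence / LeafJawPositions and the fraction
# group metersets) and a regular dose lattice (PixelData + grid geometry) is
# implemented. Sequences with defined or undefined length are supported;
# other transfer syntaxes are rejected.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_RTPLAN_STORAGE <- "1.2.840.10008.5.1.4.1.1.481.5"
UID_RTDOSE_STORAGE <- "1.2.840.10008.5.1.4.1.1.481.2"

# --- low-level parsing -------------------------------------------------

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_u32 <- function(raw, pos) {
  # as double: lengths can exceed .Machine$integer.max sentinel-wise
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

VR_LONG <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parse a dataset between byte offsets [pos, end]; returns list(elements,
# next_pos). Each element: list(group, element, vr, value_raw or items).
dcm_parse_dataset <- function(raw, pos, end, stop_at_item_delim = FALSE) {
  out <- list()
  while (pos <= end) {
    group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
    if (group == 0xFFFE && elem == 0xE00D) {  # item delimitation
      pos <- pos + 8L
      if (stop_at_item_delim) break else next
    }
    if (group == 0xFFFE && elem == 0xE0DD) {  # sequence delimitation (stray)
      pos <- pos + 8L
      next
    }
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% VR_LONG) {
      len <- dcm_u32(raw, pos + 8L)
      body <- pos + 12L
    } else {
      len <- dcm_u32(raw, pos + 6L) %% 65536
      len <- dcm_u16(raw, pos + 6L)
      body <- pos + 8L
    }
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) {  # undefined length
        p <- body
        repeat {
          g <- dcm_u16(raw, p); e <- dcm_u16(raw, p + 2L)
          if (g == 0xFFFE && e == 0xE0DD) { p <- p + 8L; break }
          if (!(g == 0xFFFE && e == 0xE000))
            stop("DICOM: expected sequence item at offset ", p)
          ilen <- dcm_u32(raw, p + 4L)
          if (ilen == 4294967295) {
            r <- dcm_parse_dataset(raw, p + 8L, length(raw),
                                   stop_at_item_delim = TRUE)
          } else {
            r <- dcm_parse_dataset(raw, p + 8L, p + 8L + ilen - 1L)
          }
          items[[length(items) + 1L]] <- r$elements
          p <- r$next_pos
        }
        pos <- p
      } else {
        p <- body; iend <- body + len - 1L
        while (p <= iend) {
          g <- dcm_u16(raw, p); e <- dcm_u16(raw, p + 2L)
          if (!(g == 0xFFFE && e == 0xE000))
            stop("DICOM: expected sequence item at offset ", p)
          ilen <- dcm_u32(raw, p + 4L)
          if (ilen == 4294967295) {
            r <- dcm_parse_dataset(raw, p + 8L, length(raw),
                                   stop_at_item_delim = TRUE)
          } else {
            r <- dcm_parse_dataset(raw, p + 8L, p + 8L + ilen - 1L)
          }
          items[[length(items) + 1L]] <- r$elements
          p <- r$next_pos
        }
        pos <- iend + 1L
      }
      out[[length(out) + 1L]] <- list(group = group, element = elem,
                                      vr = vr, items = items)
    } else {
      if (len == 4294967295)
        stop("DICOM: undefined length on non-sequence element")
      value <- if (len > 0) raw[body:(body + len - 1L)] else raw(0)
      out[[length(out) + 1L]] <- list(group = group, element = elem,
                                      vr = vr, value = value)
      pos <- body + len
    }
  }
  list(elements = out, next_pos = pos)
}

dcm_find <- function(elements, group, elem) {
  for (el in elements)
    if (el$group == group && el$element == elem) return(el)
  NULL
}

dcm_str_value <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$value
  while (length(v) && v[length(v)] %in% as.raw(c(0L, 32L)))
    v <- v[-length(v)]
  rawToChar(v)
}

dcm_num_value <- function(el) {
  s <- dcm_str_value(el)
  if (is.null(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
    # file meta group (always explicit VR LE)
    repeat {
      if (pos > length(raw)) break
      if (dcm_u16(raw, pos) != 2L) break
      r <- dcm_parse_one_meta(raw, pos)
      if (r$el$group == 2L && r$el$element == 0x0010) {
        tv <- r$el$value
        while (length(tv) && tv[length(tv)] %in% as.raw(c(0L, 32L)))
          tv <- tv[-length(tv)]
        ts <- rawToChar(tv)
        if (ts != UID_EXPLICIT_VR_LE)
          stop("DICOM: unsupported transfer syntax '", ts,
               "' (only explicit VR little endian is supported)")
      }
      pos <- r$next_pos
    }
  }
  dcm_parse_dataset(raw, pos, length(raw))$elements
}

dcm_parse_one_meta <- function(raw, pos) {
  group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
  vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
  if (vr %in% VR_LONG) {
    len <- dcm_u32(raw, pos + 8L); body <- pos + 12L
  } else {
    len <- dcm_u16(raw, pos + 6L); body <- pos + 8L
  }
  list(el = list(group = group, element = elem, vr = vr,
                 value = if (len > 0) raw[body:(body + len - 1L)] else raw(0)),
       next_pos = body + len)
}

# --- low-level writing -------------------------------------------------

enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
enc_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")

dcm_enc_elem <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    stop("DICOM encode: odd value length for (", group, ",", elem, ")")
  hdr <- c(enc_u16(group), enc_u16(elem), charToRaw(vr))
  if (vr %in% VR_LONG) {
    c(hdr, as.raw(c(0, 0)), enc_u32(length(value_raw)), value_raw)
  } else {
    c(hdr, enc_u16(length(value_raw)), value_raw)
  }
}

dcm_enc_str <- function(group, elem, vr, s, pad = " ") {
  v <- charToRaw(s)
  if (length(v) %% 2 == 1)
    v <- c(v, if (pad == "nul") as.raw(0) else charToRaw(pad))
  dcm_enc_elem(group, elem, vr, v)
}

dcm_fmt_ds <- function(x) {
  paste(vapply(x, function(v) sprintf("%.10g", v), character(1)),
        collapse = "\\")
}

dcm_enc_ds <- function(group, elem, x)
  dcm_enc_str(group, elem, "DS", dcm_fmt_ds(x))
dcm_enc_is <- function(group, elem, x)
  dcm_enc_str(group, elem, "IS", paste(as.integer(x), collapse = "\\"))
dcm_enc_sq <- function(group, elem, items) {
  body <- raw(0)
  for (it in items)
    body <- c(body, enc_u16(0xFFFE), enc_u16(0xE000), enc_u32(length(it)), it)
  body <- c(body, enc_u16(0xFFFE), enc_u16(0xE0DD), enc_u32(0))
  c(enc_u16(group), enc_u16(elem), charToRaw("SQ"), as.raw(c(0, 0)),
    as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)), body)
}

dcm_file_meta <- function(sop_class, sop_instance) {
  body <- c(
    dcm_enc_str(2, 0x0002, "UI", sop_class, pad = "nul"),
    dcm_enc_str(2, 0x0003, "UI", sop_instance, pad = "nul"),
    dcm_enc_str(2, 0x0010, "UI", UID_EXPLICIT_VR_LE, pad = "nul"))
  meta <- c(dcm_enc_elem(2, 0x0000, "UL", enc_u32(length(body))), body)
  c(raw(128), charToRaw("DICM"), meta)
}

dcm_uid <- function(suffix) paste0("1.2.826.0.1.3680043.9999.", suffix)

# --- RT Plan -----------------------------------------------------------

#' Read a DICOM-RT Plan file
#'
#' Parses a DICOM-RT Plan (explicit VR little endian) with dynamic-MLC
#' (sliding-window) beams into the validated plan model. Setup/imaging beams
#' and static (non-MLC) beams are excluded; a plan with no dynamic MLC beam,
#' or a dynamic beam lacking MLC position sequences, is an error naming the
#' beam. Leaf positions are kept in mm in IEC beam-limiting-device
#' coordinates; bank A is the larger-coordinate side.
#'
#' @param path Path to the DICOM file.
#' @param site Treatment site; overrides (or supplies, when absent) the
#'   `site=` annotation the package writes into RT Plan Description.
#' @param prescribed_dose Prescription in Gy; overrides the file's
#'   TargetPrescriptionDose.
#' @return An [rt_plan()].
#' @export
read_dicom_plan <- function(path, site = NULL, prescribed_dose = NULL) {
  ds <- dcm_read_file(path)
  label <- dcm_str_value(dcm_find(ds, 0x300A, 0x0002))
  if (is.null(label)) label <- basename(path)
  descr <- dcm_str_value(dcm_find(ds, 0x300A, 0x0004))
  if (is.null(site) && !is.null(descr) && grepl("site=", descr))
    site <- sub(".*site=([a-z_]+).*", "\\1", descr)
  if (is.null(site))
    stop("DICOM plan '", label, "': treatment site not recorded in the ",
         "file; pass `site` explicitly")
  if (is.null(prescribed_dose)) {
    drs <- dcm_find(ds, 0x300A, 0x0010)
    if (!is.null(drs) && length(drs$items))
      prescribed_dose <- dcm_num_value(
        dcm_find(drs$items[[1]], 0x300A, 0x0026))
    if (!length(prescribed_dose))
      stop("DICOM plan '", label, "': no TargetPrescriptionDose; pass ",
           "`prescribed_dose` explicitly")
  }

  # beam metersets from the fraction group
  metersets <- list()
  fgs <- dcm_find(ds, 0x300A, 0x0070)
  if (!is.null(fgs)) {
    for (fg in fgs$items) {
      rbs <- dcm_find(fg, 0x300C, 0x0004)
      if (is.null(rbs)) next
      for (rb in rbs$items) {
        num <- dcm_num_value(dcm_find(rb, 0x300C, 0x0006))
        mu <- dcm_num_value(dcm_find(rb, 0x300A, 0x0086))
        if (length(num) && length(mu))
          metersets[[as.character(num)]] <- mu
      }
    }
  }

  bs <- dcm_find(ds, 0x300A, 0x00B0)
  if (is.null(bs) || !length(bs$items))
    stop("DICOM plan '", label, "': no BeamSequence")
  beams <- list()
  for (bj in bs$items) {
    beam_num <- dcm_num_value(dcm_find(bj, 0x300A, 0x00C0))
    beam_name <- dcm_str_value(dcm_find(bj, 0x300A, 0x00C2))
    if (is.null(beam_name)) beam_name <- paste0("beam", beam_num)
    delivery <- dcm_str_value(dcm_find(bj, 0x300A, 0x00CE))
    if (!is.null(delivery) && delivery != "TREATMENT") next
    beam_type <- dcm_str_value(dcm_find(bj, 0x300A, 0x00C4))
    if (!is.null(beam_type) && beam_type != "DYNAMIC") next  # static: skip

    # leaf boundaries from the MLCX device definition
    bld <- dcm_find(bj, 0x300A, 0x00B6)
    boundaries <- NULL
    if (!is.null(bld)) {
      for (dev in bld$items) {
        if (identical(dcm_str_value(dcm_find(dev, 0x300A, 0x00B8)), "MLCX"))
          boundaries <- dcm_num_value(dcm_find(dev, 0x300A, 0x00BE))
      }
    }
    if (is.null(boundaries))
      stop("DICOM plan '", label, "': beam '", beam_name,
           "' has no MLCX leaf boundaries (unreadable plan)")

    cps <- dcm_find(bj, 0x300A, 0x0111)
    if (is.null(cps) || length(cps$items) < 2L)
      stop("DICOM plan '", label, "': beam '", beam_name,
           "' has fewer than 2 control points")
    final_cmw <- dcm_num_value(dcm_find(bj, 0x300A, 0x010E))
    if (!length(final_cmw)) final_cmw <- 1

    n_pairs <- length(boundaries) - 1L
    n_cp <- length(cps$items)
    cmf <- numeric(n_cp)
    bank_a <- matrix(NA_real_, n_cp, n_pairs)
    bank_b <- matrix(NA_real_, n_cp, n_pairs)
    jaw_x <- matrix(NA_real_, n_cp, 2)
    jaw_y <- matrix(NA_real_, n_cp, 2)
    dose_rate <- NULL
    for (i in seq_len(n_cp)) {
      cp <- cps$items[[i]]
      cmw <- dcm_num_value(dcm_find(cp, 0x300A, 0x0134))
      if (!length(cmw))
        stop("DICOM plan '", label, "': beam '", beam_name,
             "' control point ", i, " lacks CumulativeMetersetWeight")
      cmf[i] <- cmw / final_cmw
      dr <- dcm_num_value(dcm_find(cp, 0x300A, 0x0115))
      if (length(dr)) dose_rate <- dr
      bldp <- dcm_find(cp, 0x300A, 0x011A)
      if (!is.null(bldp)) {
        for (dev in bldp$items) {
          kind <- dcm_str_value(dcm_find(dev, 0x300A, 0x00B8))
          pos <- dcm_num_value(dcm_find(dev, 0x300A, 0x011C))
          if (kind == "MLCX") {
            if (length(pos) != 2L * n_pairs)
              stop("DICOM plan '", label, "': beam '", beam_name,
                   "' control point ", i, " MLCX position count mismatch")
            bank_b[i, ] <- pos[seq_len(n_pairs)]
            bank_a[i, ] <- pos[n_pairs + seq_len(n_pairs)]
          } else if (kind %in% c("X", "ASYMX")) {
            jaw_x[i, ] <- pos
          } else if (kind %in% c("Y", "ASYMY")) {
            jaw_y[i, ] <- pos
          }
        }
      }
      # DICOM allows unchanged devices to be omitted after the first CP
      if (i > 1L) {
        if (anyNA(bank_a[i, ])) { bank_a[i, ] <- bank_a[i - 1L, ]
                                  bank_b[i, ] <- bank_b[i - 1L, ] }
        if (anyNA(jaw_x[i, ])) jaw_x[i, ] <- jaw_x[i - 1L, ]
        if (anyNA(jaw_y[i, ])) jaw_y[i, ] <- jaw_y[i - 1L, ]
      }
    }
    if (anyNA(bank_a[1, ]))
      stop("DICOM plan '", label, "': beam '", beam_name,
           "' has no MLC positions at the first control point ",
           "(unreadable plan)")
    if (anyNA(jaw_x[1, ])) jaw_x[1, ] <- range(bank_b[1, ], bank_a[1, ])
    if (anyNA(jaw_y[1, ])) jaw_y[1, ] <- range(boundaries)
    for (cpi in seq_len(n_cp)[-1]) {  # fill any later gaps after defaults
      if (anyNA(jaw_x[cpi, ])) jaw_x[cpi, ] <- jaw_x[cpi - 1L, ]
      if (anyNA(jaw_y[cpi, ])) jaw_y[cpi, ] <- jaw_y[cpi - 1L, ]
    }
    mu <- metersets[[as.character(beam_num)]]
    if (is.null(mu))
      stop("DICOM plan '", label, "': beam '", beam_name,
           "' has no BeamMeterset in the fraction group")
    dcmf <- diff(cmf)
    if (any(dcmf < 0))
      stop("DICOM plan '", label, "': beam '", beam_name,
           "' cumulative meterset decreases at control point ",
           which(dcmf < 0)[1] + 1L)
    beams[[length(beams) + 1L]] <- rt_beam(
      id = beam_name, meterset = mu,
      dose_rate = if (is.null(dose_rate)) 400 else dose_rate,
      leaf_boundaries = boundaries, cmf = cmf,
      bank_a = bank_a, bank_b = bank_b, jaw_x = jaw_x, jaw_y = jaw_y)
  }
  if (!length(beams))
    stop("DICOM plan '", label, "': no dynamic MLC beams (only ",
         "sliding-window plans are supported)")
  rt_plan(id = label, site = site, prescribed_dose = prescribed_dose,
          beams = beams)
}

#' Write a plan as a DICOM-RT Plan file
#'
#' Emits the subset of RT Plan carried by the plan model (beams, control
#' points, MLC and jaw positions, fraction-group metersets, target
#' prescription); the treatment site is recorded as `site=<site>` in RT Plan
#' Description so that [read_dicom_plan()] round-trips the full model.
#'
#' @param plan An [rt_plan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dicom_plan <- function(plan, path) {
  beam_items <- lapply(seq_along(plan$beams), function(bi) {
    b <- plan$beams[[bi]]
    n_pairs <- ncol(b$bank_a)
    devs <- list(
      c(dcm_enc_str(0x300A, 0x00B8, "CS", "ASYMX"),
        dcm_enc_is(0x300A, 0x00BC, 1)),
      c(dcm_enc_str(0x300A, 0x00B8, "CS", "ASYMY"),
        dcm_enc_is(0x300A, 0x00BC, 1)),
      c(dcm_enc_str(0x300A, 0x00B8, "CS", "MLCX"),
        dcm_enc_is(0x300A, 0x00BC, n_pairs),
        dcm_enc_ds(0x300A, 0x00BE, b$leaf_boundaries)))
    cp_items <- lapply(seq_along(b$cmf), function(i) {
      pos_devs <- list(
        c(dcm_enc_str(0x300A, 0x00B8, "CS", "ASYMX"),
          dcm_enc_ds(0x300A, 0x011C, b$jaw_x[i, ])),
        c(dcm_enc_str(0x300A, 0x00B8, "CS", "ASYMY"),
          dcm_enc_ds(0x300A, 0x011C, b$jaw_y[i, ])),
        c(dcm_enc_str(0x300A, 0x00B8, "CS", "MLCX"),
          dcm_enc_ds(0x300A, 0x011C, c(b$bank_b[i, ], b$bank_a[i, ]))))
      body <- c(dcm_enc_is(0x300A, 0x0112, i - 1L),
                if (i == 1L) dcm_enc_ds(0x300A, 0x0115, b$dose_rate),
                dcm_enc_ds(0x300A, 0x0134, b$cmf[i]),
                dcm_enc_sq(0x300A, 0x011A, pos_devs))
      body
    })
    c(dcm_enc_is(0x300A, 0x00C0, bi),
      dcm_enc_str(0x300A, 0x00C2, "LO", b$id),
      dcm_enc_str(0x300A, 0x00C4, "CS", "DYNAMIC"),
      dcm_enc_str(0x300A, 0x00C6, "CS", "PHOTON"),
      dcm_enc_str(0x300A, 0x00CE, "CS", "TREATMENT"),
      dcm_enc_ds(0x300A, 0x010E, 1),
      dcm_enc_is(0x300A, 0x0110, length(b$cmf)),
      dcm_enc_sq(0x300A, 0x00B6, devs),
      dcm_enc_sq(0x300A, 0x0111, cp_items))
  })
  ref_beam_items <- lapply(seq_along(plan$beams), function(bi) {
    c(dcm_enc_is(0x300C, 0x0006, bi),
      dcm_enc_ds(0x300A, 0x0086, plan$beams[[bi]]$meterset))
  })
  fraction_item <- c(dcm_enc_is(0x300A, 0x0071, 1),
                     dcm_enc_is(0x300A, 0x0078, 1),
                     dcm_enc_is(0x300A, 0x0080, length(plan$beams)),
                     dcm_enc_sq(0x300C, 0x0004, ref_beam_items))
  dose_ref_item <- c(dcm_enc_is(0x300A, 0x0012, 1),
                     dcm_enc_str(0x300A, 0x0014, "CS", "SITE"),
                     dcm_enc_ds(0x300A, 0x0026, plan$prescribed_dose))
  sop_instance <- dcm_uid(paste0("1.", abs(sum(utf8ToInt(plan$id)))))
  body <- c(
    dcm_enc_str(0x0008, 0x0016, "UI", UID_RTPLAN_STORAGE, pad = "nul"),
    dcm_enc_str(0x0008, 0x0018, "UI", sop_instance, pad = "nul"),
    dcm_enc_str(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_enc_str(0x300A, 0x0002, "SH", plan$id),
    dcm_enc_str(0x300A, 0x0004, "LO", paste0("site=", plan$site)),
    dcm_enc_str(0x300A, 0x000C, "CS", "PATIENT"),
    dcm_enc_sq(0x300A, 0x0010, list(dose_ref_item)),
    dcm_enc_sq(0x300A, 0x0070, list(fraction_item)),
    dcm_enc_sq(0x300A, 0x00B0, beam_items))
  out <- c(dcm_file_meta(UID_RTPLAN_STORAGE, sop_instance), body)
  writeBin(out, path)
  invisible(path)
}

# --- RT Dose -----------------------------------------------------------

#' Read a DICOM-RT Dose file into a dose grid
#'
#' Supports explicit-VR-little-endian RT Dose with 16- or 32-bit unsigned
#' pixel data on an axis-aligned regular lattice.
#'
#' @param path Path to the DICOM file.
#' @return A [dose_grid()].
#' @export
read_dicom_dose <- function(path) {
  ds <- dcm_read_file(path)
  rows <- dcm_u16_value(dcm_find(ds, 0x0028, 0x0010))
  cols <- dcm_u16_value(dcm_find(ds, 0x0028, 0x0011))
  frames <- as.integer(dcm_num_value(dcm_find(ds, 0x0028, 0x0008)))
  bits <- dcm_u16_value(dcm_find(ds, 0x0028, 0x0100))
  ipp <- dcm_num_value(dcm_find(ds, 0x0020, 0x0032))
  ps <- dcm_num_value(dcm_find(ds, 0x0028, 0x0030))  # row spacing, col spacing
  gfo <- dcm_num_value(dcm_find(ds, 0x3004, 0x000C))
  scaling <- dcm_num_value(dcm_find(ds, 0x3004, 0x000E))
  px <- dcm_find(ds, 0x7FE0, 0x0010)
  if (is.null(px)) stop("DICOM dose: no PixelData")
  n <- rows * cols * frames
  if (bits == 16) {
    v <- readBin(px$value, "integer", n = n, size = 2, signed = FALSE,
                 endian = "little")
  } else if (bits == 32) {
    v <- readBin(px$value, "integer", n = n, size = 4, endian = "little")
    v <- ifelse(v < 0, v + 4294967296, v)
  } else stop("DICOM dose: unsupported BitsAllocated ", bits)
  dz <- if (frames > 1) diff(gfo[1:2]) else 1
  # pixel order: frame (z), then row (y), then column (x, fastest)
  arr <- array(v * scaling, dim = c(cols, rows, frames))
  dose_grid(origin = ipp, spacing = c(ps[2], ps[1], dz), values = arr)
}

dcm_u16_value <- function(el) {
  if (is.null(el)) stop("DICOM dose: missing image geometry element")
  readBin(el$value, "integer", n = 1, size = 2, signed = FALSE,
          endian = "little")
}

#' Write a dose grid as a DICOM-RT Dose file
#'
#' @param grid A [dose_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dicom_dose <- function(grid, path) {
  d <- dim(grid$values)
  scaling <- max(grid$values, 1e-12) / (2^31 - 1)
  q <- as.integer(round(grid$values / scaling))
  pix <- writeBin(as.vector(q), raw(), size = 4, endian = "little")
  sop_instance <- dcm_uid("2.1")
  body <- c(
    dcm_enc_str(0x0008, 0x0016, "UI", UID_RTDOSE_STORAGE, pad = "nul"),
    dcm_enc_str(0x0008, 0x0018, "UI", sop_instance, pad = "nul"),
    dcm_enc_str(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_enc_ds(0x0020, 0x0032, grid$origin),
    dcm_enc_elem(0x0028, 0x0008, "IS",
                 charToRaw(formatC(d[3], width = 2))),
    dcm_enc_elem(0x0028, 0x0010, "US", enc_u16(d[2])),
    dcm_enc_elem(0x0028, 0x0011, "US", enc_u16(d[1])),
    dcm_enc_ds(0x0028, 0x0030, c(grid$spacing[2], grid$spacing[1])),
    dcm_enc_elem(0x0028, 0x0100, "US", enc_u16(32)),
    dcm_enc_elem(0x0028, 0x0101, "US", enc_u16(32)),
    dcm_enc_elem(0x0028, 0x0102, "US", enc_u16(31)),
    dcm_enc_elem(0x0028, 0x0103, "US", enc_u16(0)),
    dcm_enc_str(0x3004, 0x0002, "CS", "GY"),
    dcm_enc_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_enc_ds(0x3004, 0x000C,
               grid$origin[3] + grid$spacing[3] * (seq_len(d[3]) - 1) -
                 grid$origin[3]),
    dcm_enc_ds(0x3004, 0x000E, scaling),
    dcm_enc_elem(0x7FE0, 0x0010, "OW", pix))
  writeBin(c(dcm_file_meta(UID_RTDOSE_STORAGE, sop_instance), body), path)
  invisible(path)
}
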