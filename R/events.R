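#' Build an event schedule from a NONMEM-convention event table
#'
#' Clinical trials are described by an *event schedule*: one row per dosing or
#' measurement event, using the NONMEM variable convention (`time`, `amt`,
#' `rate`, `ii`, `addl`, `cmt`, `evid`, `ss`, `dv`).  The schedule drives every
#' solver in the package.
#'
#' Required columns are `time`, `cmt` and `evid`; `id` defaults to a single
#' subject and `amt`, `rate`, `ii`, `addl`, `ss` default to 0.  `dv` holds the
#' observed value at measurement rows (`evid = 0`) and is forced to `NA` on
#' dose rows.  Any other column (e.g. body weight `wt`) is kept as a covariate.
#' Only `evid` codes 0 (measurement) and 1 (dosing) are defined; any other code
#' is rejected.
#'
#' @param rows a data frame of event records.
#' @param n_cmt number of model compartments (validates `cmt`).
#' @param F per-compartment bioavailability fractions in (0, 1].
#' @param tlag per-compartment dosing lag times (h, >= 0).
#' @return an object of class `pmx_events`: a list with elements `records`
#'   (the normalized data frame), `F`, `tlag`, `n_cmt` and `subjects` (a data
#'   frame with the first/last record index of each subject's block).
#' @examples
#' ev <- read_events_table(data.frame(
#'   time = 0, amt = 1200, cmt = 1, evid = 1, ii = 12, addl = 13))
#' ev
#' @export
read_events_table <- function(rows, n_cmt = 3, F = rep(1, n_cmt),
                              tlag = rep(0, n_cmt)) {
  stopifnot(is.data.frame(rows))
  need <- c("time", "cmt", "evid")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("missing required event columns: ", paste(miss, collapse = ", "))
  rec <- rows
  if (is.null(rec$id)) rec$id <- 1L
  for (col in c("amt", "rate", "ii", "addl", "ss")) {
    if (is.null(rec[[col]])) rec[[col]] <- 0
    rec[[col]][is.na(rec[[col]])] <- 0
  }
  if (is.null(rec$dv)) rec$dv <- NA_real_
  for (col in c("time", "amt", "rate", "ii", "addl", "cmt", "evid", "ss",
                "dv"))
    rec[[col]] <- as.numeric(rec[[col]])

  if (!all(rec$evid %in% c(0, 1)))
    stop("unknown evid code; defined are: Type of event: (0) measurement, (1) dosing")
  if (any(rec$time < 0)) stop("negative event time")
  if (any(rec$amt < 0)) stop("negative dose amount (amt)")
  if (any(rec$rate < 0)) stop("negative infusion rate")
  if (any(rec$ii < 0)) stop("negative interdose interval (ii)")
  if (any(rec$addl < 0) || any(rec$addl != round(rec$addl)))
    stop("addl must be a non-negative integer")
  if (any(rec$addl > 0 & rec$ii <= 0))
    stop("addl > 0 requires a positive interdose interval ii")
  if (any(rec$addl > 0 & rec$evid != 1))
    stop("addl > 0 is only defined for dosing events (evid = 1)")
  if (any(rec$ss == 1 & (rec$evid != 1 | rec$ii <= 0)))
    stop("ss = 1 requires a dosing event (evid = 1) with ii > 0")
  if (!all(rec$ss %in% c(0, 1))) stop("ss must be 0 or 1")
  if (any(rec$amt > 0 & rec$evid != 1))
    stop("amt > 0 is only defined for dosing events (evid = 1)")
  if (any(rec$cmt < 1 | rec$cmt > n_cmt | rec$cmt != round(rec$cmt)))
    stop("cmt must be a 1-based compartment index <= ", n_cmt)
  rec$dv[rec$evid == 1] <- NA_real_

  if (length(F) != n_cmt || length(tlag) != n_cmt)
    stop("F and tlag must have one entry per compartment")
  if (any(F <= 0 | F > 1)) stop("bioavailability fractions F must lie in (0, 1]")
  if (any(tlag < 0)) stop("lag times tlag must be >= 0")

  # group by subject, preserving input order of subjects and of rows within
  ord <- order(match(rec$id, unique(rec$id)))
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  for (sid in unique(rec$id)) {
    ti <- rec$time[rec$id == sid]
    if (is.unsorted(ti))
      stop("event times must be non-decreasing within subject ", sid)
  }
  front <- intersect(c("id", "time", "amt", "rate", "ii", "addl", "cmt",
                       "evid", "ss", "dv"), names(rec))
  rec <- rec[, c(front, setdiff(names(rec), front)), drop = FALSE]
  structure(list(records = rec, F = F, tlag = tlag, n_cmt = n_cmt,
                 subjects = subject_ranges(rec)),
            class = "pmx_events")
}

subject_ranges <- function(rec) {
  ids <- unique(rec$id)
  data.frame(id = ids,
             start = match(ids, rec$id),
             end = length(rec$id) - match(ids, rev(rec$id)) + 1L)
}

#' @export
print.pmx_events <- function(x, ...) {
  n <- nrow(x$records)
  cat("<pmx_events> ", n, " events, ",
      nrow(x$subjects), " subject(s), ",
      sum(x$records$evid == 1), " dose row(s), ",
      sum(x$records$evid == 0), " observation row(s)\n", sep = "")
  print(utils::head(x$records, 8))
  if (n > 8) cat("... and", n - 8, "more rows\n")
  invisible(x)
}

#' Read / write an events CSV
#'
#' The CSV uses the header `id,time,amt,rate,ii,addl,cmt,evid,ss,dv` plus any
#' covariate columns; blank cells and `"."` are treated as missing and take
#' the documented defaults.
#'
#' @param path file path.
#' @param ... passed on to [read_events_table()].
#' @return `read_events_csv()` returns a `pmx_events` object;
#'   `write_events_csv()` invisibly returns `path`.
#' @export
read_events_csv <- function(path, ...) {
  rows <- utils::read.csv(path, na.strings = c("", ".", "NA"))
  read_events_table(rows, ...)
}

#' @rdname read_events_csv
#' @param schedule a `pmx_events` object.
#' @export
write_events_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "pmx_events"))
  rec <- schedule$records
  for (col in names(rec))  # full double precision so re-reading is lossless
    if (is.double(rec[[col]]))
      rec[[col]] <- ifelse(is.na(rec[[col]]), NA,
                           formatC(rec[[col]], digits = 17, format = "g"))
  utils::write.csv(rec, path, row.names = FALSE, na = ".", quote = FALSE)
  invisible(path)
}

#' Expand additional doses
#'
#' Replaces every dose row carrying `addl = k > 0` by `k + 1` identical dose
#' rows at times `t, t + ii, ..., t + k*ii`, each with `addl = 0`.  Expanded
#' copies keep `ss = 0` (only the originating dose initializes a steady state)
#' and sort *after* any explicit record at the same time, so a trough
#' observation listed at the next nominal dose time reads the pre-dose state.
#'
#' @param schedule a `pmx_events` object.
#' @return a `pmx_events` object with `addl` fully expanded.
#' @examples
#' ev <- read_events_table(data.frame(
#'   time = 0, amt = 1200, cmt = 1, evid = 1, ii = 12, addl = 13))
#' nrow(expand_additional_doses(ev)$records)  # 14 dose events
#' @export
expand_additional_doses <- function(schedule) {
  stopifnot(inherits(schedule, "pmx_events"))
  rec <- schedule$records
  if (!any(rec$addl > 0)) return(schedule)
  out <- vector("list", nrow(schedule$subjects))
  for (s in seq_len(nrow(schedule$subjects))) {
    blk <- rec[schedule$subjects$start[s]:schedule$subjects$end[s], ,
               drop = FALSE]
    blk$.ord <- seq_len(nrow(blk))
    extras <- list()
    for (i in which(blk$addl > 0)) {
      k <- blk$addl[i]
      cp <- blk[rep(i, k), , drop = FALSE]
      cp$time <- blk$time[i] + seq_len(k) * blk$ii[i]
      cp$ss <- 0
      cp$.ord <- nrow(blk) + seq_along(cp$time)  # ties sort after originals
      extras[[length(extras) + 1L]] <- cp
    }
    blk$addl <- 0
    ext <- do.call(rbind, extras)
    ext$addl <- 0
    blk <- rbind(blk, ext)
    blk <- blk[order(blk$time, blk$.ord), , drop = FALSE]
    blk$.ord <- NULL
    out[[s]] <- blk
  }
  rec2 <- do.call(rbind, out)
  rownames(rec2) <- NULL
  structure(list(records = rec2, F = schedule$F, tlag = schedule$tlag,
                 n_cmt = schedule$n_cmt, subjects = subject_ranges(rec2)),
            class = "pmx_events")
}

#' Compile one subject's events into a solve plan
#'
#' Turns a (fully expanded) schedule into the chronological sequence of
#' primitive actions a solver executes: advance the state to a time point,
#' apply a bolus (bioavailability-scaled, at `time + tlag`), switch a
#' zero-order infusion on or off (duration `F * amt / rate`), initialize from a
#' periodic steady state, and record the state at each event row.  Dose rows
#' record the post-dose state at the event's nominal time; a lag-shifted dose
#' is applied later, so the dose row (and any observation inside the lag
#' window) reads the pre-absorption state.  Records sharing a timestamp are
#' executed in input order; deferred dose actions maturing at a timestamp are
#' applied before records at that timestamp.
#'
#' @param schedule a `pmx_events` object with `addl` expanded.
#' @param subject subject id (defaults to the first subject).
#' @return a data frame with columns `time`, `op` (0 record-only, 1 bolus,
#'   2 infusion start, 3 infusion end, 4 steady-state bolus, 5 steady-state
#'   infusion), `cmt`, `amt`, `rate`, `ii`, `record` (output column index, 0
#'   for pure actions) and `theta` (the subject-local event index whose
#'   parameters govern propagation into this row).
#' @export
event_grid <- function(schedule, subject = schedule$subjects$id[1]) {
  stopifnot(inherits(schedule, "pmx_events"))
  if (any(schedule$records$addl > 0))
    stop("expand additional doses before building a solve plan")
  s <- match(subject, schedule$subjects$id)
  if (is.na(s)) stop("unknown subject id: ", subject)
  blk <- schedule$records[schedule$subjects$start[s]:schedule$subjects$end[s], ,
                          drop = FALSE]
  F <- schedule$F
  tlag <- schedule$tlag
  rows <- list()
  add <- function(time, op, cmt = 0, amt = 0, rate = 0, ii = 0, record = 0,
                  theta = 0, pri = 1) {
    rows[[length(rows) + 1L]] <<- c(time = time, op = op, cmt = cmt, amt = amt,
                                    rate = rate, ii = ii, record = record,
                                    theta = theta, pri = pri)
  }
  for (j in seq_len(nrow(blk))) {
    e <- blk[j, ]
    if (e$evid == 0) {
      add(e$time, 0, record = j, theta = j)
    } else if (e$rate > 0) {
      if (e$amt <= 0)
        stop("infusion with rate > 0 requires amt > 0 (undefined duration)")
      famt <- F[e$cmt] * e$amt
      tinf <- famt / e$rate
      if (e$ss == 1) {
        add(e$time, 5, cmt = e$cmt, amt = famt, rate = e$rate, ii = e$ii,
            record = j, theta = j)
      } else {
        add(e$time, 0, record = j, theta = j)
      }
      add(e$time + tlag[e$cmt], 2, cmt = e$cmt, rate = e$rate, theta = j,
          pri = 0)
      add(e$time + tlag[e$cmt] + tinf, 3, cmt = e$cmt, rate = e$rate,
          theta = j, pri = 0)
    } else if (e$ss == 1) {
      add(e$time, 4, cmt = e$cmt, amt = F[e$cmt] * e$amt, ii = e$ii,
          record = j, theta = j)
    } else if (tlag[e$cmt] > 0) {
      add(e$time, 0, record = j, theta = j)
      add(e$time + tlag[e$cmt], 1, cmt = e$cmt, amt = F[e$cmt] * e$amt,
          theta = j, pri = 0)
    } else {
      add(e$time, 1, cmt = e$cmt, amt = F[e$cmt] * e$amt, record = j,
          theta = j)
    }
  }
  plan <- as.data.frame(do.call(rbind, rows))
  plan <- plan[order(plan$time, plan$pri, seq_len(nrow(plan))), , drop = FALSE]
  plan$pri <- NULL
  rownames(plan) <- NULL
  plan
}

#' Indices of measurement rows
#'
#' Only measurement events (`evid = 0`) enter the likelihood; this returns
#' their positions in the schedule, per subject, in order.
#'
#' @param schedule a `pmx_events` object.
#' @return an integer vector of row indices into `schedule$records`, named by
#'   subject id.
#' @export
observation_view <- function(schedule) {
  stopifnot(inherits(schedule, "pmx_events"))
  idx <- which(schedule$records$evid == 0)
  names(idx) <- as.character(schedule$records$id[idx])
  idx
}
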