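#' Extract co-location activities from parsed RTLS events
#'
#' Builds the atomic units of care pathways: maximal time segments during
#' which a patient's room and the multiset of co-located resource types are
#' both constant. A new activity begins exactly when the patient changes room
#' or the set of resource types present with the patient changes. A swap
#' between two units of the same type does not split an activity (pathways
#' are type-level); two units of the same type present simultaneously yield a
#' multiset label such as `"Provider+Provider"`.
#'
#' Timestamps are floored to whole minutes before segmentation; co-location
#' is evaluated on half-open minute intervals `[max(starts), min(ends))`, so
#' zero-length intersections are not activities. Patients with no co-located
#' time at all are excluded and reported in the `no_colocation` attribute.
#'
#' @param patient_events,resource_events data.tables as returned by
#'   [parse_rtls_logs()].
#' @param min_overlap minimum activity duration in minutes (default 1);
#'   shorter segments are discarded as spurious co-location.
#' @return a data.table of activity observations with columns `patient_id`,
#'   `ordinal` (0-based position in the visit), `resource_types` (canonical
#'   sorted `+`-joined multiset label), `room_id`, `start`, `end` (minutes
#'   from the earliest event in the logs) and `duration` (integer minutes).
#'   Attribute `no_colocation` lists patients without any co-location.
#' @export
extract_activities <- function(patient_events, resource_events,
                               min_overlap = 1) {
  pe <- data.table::as.data.table(patient_events)
  re <- data.table::as.data.table(resource_events)
  if (nrow(pe) == 0)
    return(structure(
      data.table::data.table(patient_id = character(), ordinal = integer(),
                             resource_types = character(), room_id = character(),
                             start = numeric(), end = numeric(),
                             duration = numeric()),
      no_colocation = character()))

  base <- min(c(pe$move_start, re$start))
  pe2 <- data.table::data.table(
    pe_id = seq_len(nrow(pe)),
    patient_id = pe$patient_id,
    room_id = pe$room_id,
    room_name = pe$room_name,
    ps = minutes_since(pe$move_start, base),
    pend = minutes_since(pe$move_end, base)
  )
  re2 <- data.table::data.table(
    room_name = re$room_name,
    type = re$resource_type,
    rs = minutes_since(re$start, base),
    rend = minutes_since(re$end, base)
  )
  ## keep original interval endpoints; the non-equi join overwrites the
  ## joined columns with the i-side values
  re2[, `:=`(rs0 = rs, rend0 = rend)]

  ## patient-event x resource-event overlaps in the same room
  ov <- re2[pe2, on = .(room_name, rs < pend, rend > ps),
            nomatch = NULL, allow.cartesian = TRUE,
            .(pe_id = i.pe_id, type = x.type,
              s = pmax(x.rs0, i.ps), e = pmin(x.rend0, i.pend))]
  ov <- ov[e > s]

  no_colo <- setdiff(pe2$patient_id, pe2[pe_id %in% unique(ov$pe_id), patient_id])
  if (nrow(ov) == 0)
    return(structure(
      data.table::data.table(patient_id = character(), ordinal = integer(),
                             resource_types = character(), room_id = character(),
                             start = numeric(), end = numeric(),
                             duration = numeric()),
      no_colocation = sort(unique(pe2$patient_id))))

  ## segment each patient event at intersection endpoints
  bnd <- unique(data.table::rbindlist(list(ov[, .(pe_id, t = s)],
                                           ov[, .(pe_id, t = e)])))
  data.table::setorder(bnd, pe_id, t)
  segs <- bnd[, if (.N >= 2) .(seg_s = t[-.N], seg_e = t[-1]), by = pe_id]

  ## resource-type multiset covering each segment (duplicates kept: two units
  ## of one type present at once count twice)
  cov <- ov[segs, on = .(pe_id, s <= seg_s, e >= seg_e),
            nomatch = NULL, allow.cartesian = TRUE,
            .(pe_id = i.pe_id, seg_s = i.seg_s, seg_e = i.seg_e, type = x.type)]
  obs <- cov[, .(label = multiset_label(type)),
             by = .(pe_id, seg_s, seg_e)]

  obs <- obs[pe2, on = "pe_id", nomatch = NULL,
             .(patient_id = i.patient_id, room_id = i.room_id,
               start = seg_s, end = seg_e, label)]
  data.table::setorder(obs, patient_id, start, end)

  ## merge contiguous segments with identical room and multiset
  obs[, run := cumsum(
    !(patient_id == data.table::shift(patient_id, fill = "") &
        room_id == data.table::shift(room_id, fill = "") &
        label == data.table::shift(label, fill = "") &
        start == data.table::shift(end, fill = -Inf)))]
  obs <- obs[, .(patient_id = patient_id[1], room_id = room_id[1],
                 resource_types = label[1], start = start[1], end = end[.N]),
             by = run][, run := NULL]
  obs[, duration := end - start]
  obs <- obs[duration >= min_overlap]

  no_colo <- sort(unique(c(no_colo, setdiff(pe2$patient_id, obs$patient_id))))
  data.table::setorder(obs, patient_id, start)
  obs[, ordinal := seq_len(.N) - 1L, by = patient_id]
  data.table::setcolorder(obs, c("patient_id", "ordinal", "resource_types",
                                 "room_id", "start", "end", "duration"))
  structure(obs[], no_colocation = no_colo)
}
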