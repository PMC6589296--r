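#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Deterministic event core of the ED/PESU patient-flow simulation. All
// stochastic inputs (arrival times, bed-holding and total treatment times,
// PESU eligibility and stay draws) are sampled in R beforehand, so a given
// input table always yields a bit-identical trajectory.
//
// Flow contract:
//  * non-eligible patients join a single FIFO queue for ED beds, hold a bed
//    for bed_hold (= beta * T) and are discharged at service_start + T;
//  * an eligible patient finding a free PESU space enters it on arrival and
//    holds it for stay_direct;
//  * an eligible patient finding the PESU full follows the ED path AND
//    joins a FIFO transfer list: if a PESU space frees while the patient is
//    still queueing for, or holding, an ED bed, the ED resource is released
//    immediately and the patient moves to the PESU for stay_transfer.
//
// Patient status codes: 0 = queued for ED bed, 1 = in ED bed,
// 2 = ED pathway complete, 3 = in/through PESU, -1 = not yet arrived.

struct Ev {
  double t;
  long long seq;
  int type; // 1 = ED bed release, 2 = PESU release
  int id;
};
struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

// [[Rcpp::export]]
List des_core(NumericVector arrival, LogicalVector eligible,
              NumericVector bed_hold, NumericVector treat_total,
              NumericVector stay_direct, NumericVector stay_transfer,
              int ed_beds, int pesu_capacity, double horizon,
              double warmup) {
  const int n = arrival.size();
  std::vector<int> status(n, -1);
  NumericVector sstart(n, NA_REAL), depart(n, NA_REAL),
      transfer_time(n, NA_REAL);
  LogicalVector in_pesu(n, false), transferred(n, false);

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> heap;
  std::deque<int> edq, transferq;
  long long seq = 0;
  int ed_busy = 0, pesu_busy = 0;
  double t_last = 0.0, ed_area = 0.0, pesu_area = 0.0;
  bool ok = true;

  auto advance = [&](double t) {
    double lo = std::max(t_last, warmup), hi = std::min(t, horizon);
    if (hi > lo) {
      ed_area += ed_busy * (hi - lo);
      pesu_area += pesu_busy * (hi - lo);
    }
    t_last = t;
    if (ed_busy < 0 || ed_busy > ed_beds || pesu_busy < 0 ||
        pesu_busy > pesu_capacity)
      ok = false;
  };

  auto start_service = [&](int i, double t) {
    ed_busy++;
    status[i] = 1;
    sstart[i] = t;
    heap.push({t + bed_hold[i], ++seq, 1, i});
  };

  auto pull_queue = [&](double t) {
    while (!edq.empty() && ed_busy < ed_beds) {
      int j = edq.front();
      edq.pop_front();
      if (status[j] == 0) start_service(j, t);
    }
  };

  int ai = 0;
  const double INF = std::numeric_limits<double>::infinity();
  while (true) {
    double ta = (ai < n) ? arrival[ai] : INF;
    double te = heap.empty() ? INF : heap.top().t;
    double tnext = std::min(ta, te);
    if (!(tnext <= horizon)) break;

    if (ta <= te) { // arrival (arrivals precede same-time releases)
      int i = ai++;
      double t = ta;
      advance(t);
      if (eligible[i] && pesu_busy < pesu_capacity) {
        pesu_busy++;
        status[i] = 3;
        in_pesu[i] = true;
        depart[i] = t + stay_direct[i];
        heap.push({depart[i], ++seq, 2, i});
      } else {
        if (eligible[i]) transferq.push_back(i);
        if (ed_busy < ed_beds && edq.empty()) {
          start_service(i, t);
        } else {
          status[i] = 0;
          edq.push_back(i);
        }
      }
    } else { // scheduled release
      Ev ev = heap.top();
      heap.pop();
      if (ev.type == 1) {
        if (status[ev.id] != 1) continue; // stale: patient moved to PESU
        advance(ev.t);
        ed_busy--;
        status[ev.id] = 2;
        depart[ev.id] = sstart[ev.id] + treat_total[ev.id];
        pull_queue(ev.t);
      } else { // PESU release
        advance(ev.t);
        pesu_busy--;
        while (!transferq.empty() && pesu_busy < pesu_capacity) {
          int j = transferq.front();
          transferq.pop_front();
          if (status[j] == 0 || status[j] == 1) {
            bool had_bed = (status[j] == 1);
            status[j] = 3;
            in_pesu[j] = true;
            transferred[j] = true;
            transfer_time[j] = ev.t;
            depart[j] = ev.t + stay_transfer[j];
            pesu_busy++;
            heap.push({depart[j], ++seq, 2, j});
            if (had_bed) {
              ed_busy--;
              pull_queue(ev.t);
            }
            break;
          }
        }
      }
    }
  }
  advance(horizon);

  double win = horizon - warmup;
  double ed_util = (win > 0 && ed_beds > 0) ? ed_area / (ed_beds * win) : NA_REAL;
  double pesu_util = (win > 0 && pesu_capacity > 0)
                         ? pesu_area / (pesu_capacity * win)
                         : NA_REAL;

  IntegerVector st(status.begin(), status.end());
  return List::create(
      _["status"] = st, _["service_start"] = sstart, _["depart"] = depart,
      _["in_pesu"] = in_pesu, _["transferred"] = transferred,
      _["transfer_time"] = transfer_time, _["ed_utilization"] = ed_util,
      _["pesu_utilization"] = pesu_util, _["capacity_ok"] = ok);
}
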