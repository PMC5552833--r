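#include <Rcpp.h>
using namespace Rcpp;

// Build drug-coverage episodes from dispensing records sorted by (group, day).
//
// Each record covers `cover` days at 1 DDD/day starting at `day`. With
// `stockpile` (the default), a purchase arriving while coverage remains
// (day <= current coverage end) extends the episode from the current
// coverage end; without it, remaining supply is discarded and coverage runs
// to max(current end, day + cover). A purchase more than `grace` days after
// the coverage end opens a new episode; a purchase within the grace window
// bridges the gap (the bridged days count as covered). `group` encodes
// person x drug class; episodes never span groups. Returns half-open
// [start, end) episodes plus the cumulative covered days accrued before
// each episode within its group, which lets callers evaluate cumulative
// exposure at any time point without rescanning.
//
// [[Rcpp::export]]
DataFrame build_coverage_episodes(IntegerVector group, IntegerVector day,
                                  IntegerVector cover,
                                  bool stockpile = true, int grace = 0) {
  int n = group.size();
  std::vector<int> g_out, s_out, e_out;
  std::vector<double> cum_out;
  if (n > 0) {
    g_out.reserve(n); s_out.reserve(n); e_out.reserve(n); cum_out.reserve(n);
    int cur_g = group[0];
    long cur_s = day[0];
    long cur_e = (long)day[0] + cover[0];
    double cum = 0.0;
    for (int i = 1; i <= n; ++i) {
      bool new_group = (i < n) && (group[i] != cur_g);
      bool gap = (i < n) && !new_group && ((long)day[i] > cur_e + grace);
      if (i == n || new_group || gap) {
        g_out.push_back(cur_g);
        s_out.push_back((int)cur_s);
        e_out.push_back((int)cur_e);
        cum_out.push_back(cum);
        cum += (double)(cur_e - cur_s);
        if (i == n) break;
        if (new_group) { cur_g = group[i]; cum = 0.0; }
        cur_s = day[i];
        cur_e = (long)day[i] + cover[i];
      } else if ((long)day[i] > cur_e) {
        // within the grace window: bridge the gap, coverage runs on
        cur_e = (long)day[i] + cover[i];
      } else if (stockpile) {
        // purchase while covered (or abutting): extend from coverage end
        cur_e += cover[i];
      } else {
        // remaining supply discarded; coverage restarts at the purchase
        long alt = (long)day[i] + cover[i];
        if (alt > cur_e) cur_e = alt;
      }
    }
  }
  return DataFrame::create(_["group"] = wrap(g_out),
                           _["ep_start"] = wrap(s_out),
                           _["ep_end"] = wrap(e_out),
                           _["cum_before"] = wrap(cum_out));
}
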