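// Dynamic program for reconciling a binary rooted gene tree into a
// time-sliced species tree under the 35-row event model.
//
// Cells c_min(e, d) are indexed by gene-tree edge e (identified with the
// vertex below it; the root vertex names the root edge e0) and tube d of
// the sliced species tree.  Edges are visited children-first, tubes in
// order of descending time slice; within a slice the outgroup segment is
// visited first for e != e0 and last for e0, because the sleep row reads
// the outgroup cell of its own slice while the big-gain row (only at e0)
// reads in-group cells of its own slice.
//
// Special handling at the root tube d0: the duplication row (12) demands
// that neither copy exits through the outgroup rows (10/11), and the free
// root duplication row (13) demands that at least one copy does.  For
// every cell at d0 we therefore also keep the minimum over non-exit rows
// and the minimum over the exit rows.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Costs {
  double loss, dupl, gain, tr_with, tr_without, sleep, gain_big;
};

struct STree {
  int n, d0, n_slices;
  std::vector<int> parent;                  // 0-based, -1 for d0
  std::vector<std::vector<int> > children;
  std::vector<int> slice;                   // 1-based slice index
  std::vector<bool> ogr, term;
  std::vector<std::vector<int> > slices;    // tubes per slice
  std::vector<int> ogr_in_slice;            // -1 if absent
  std::vector<std::vector<int> > dist;
};

struct GTree {
  int n, root;
  std::vector<std::vector<int> > children;
  std::vector<int> order;                   // postorder
  std::vector<int> leaf_tube;               // terminal tube id, -1
};

static STree unpack_stree(const List &s0) {
  STree S;
  IntegerVector par = s0["parent"];
  List ch = s0["children"];
  IntegerVector sl = s0["slice"];
  LogicalVector og = s0["is_outgroup"];
  LogicalVector tm = s0["terminal"];
  IntegerVector ogs = s0["outgroup_in_slice"];
  List slc = s0["slices"];
  IntegerMatrix dm = s0["dist"];
  S.n = par.size();
  S.d0 = as<int>(s0["root_tube"]) - 1;
  S.n_slices = as<int>(s0["n_slices"]);
  S.parent.resize(S.n);
  S.children.resize(S.n);
  S.slice.resize(S.n);
  S.ogr.resize(S.n);
  S.term.resize(S.n);
  for (int i = 0; i < S.n; i++) {
    S.parent[i] = par[i] - 1;
    S.slice[i] = sl[i];
    S.ogr[i] = og[i];
    S.term[i] = tm[i];
    IntegerVector c = ch[i];
    for (int j = 0; j < c.size(); j++) S.children[i].push_back(c[j] - 1);
  }
  S.slices.resize(S.n_slices);
  for (int s = 0; s < S.n_slices; s++) {
    IntegerVector t = slc[s];
    for (int j = 0; j < t.size(); j++) S.slices[s].push_back(t[j] - 1);
  }
  S.ogr_in_slice.resize(S.n_slices);
  for (int s = 0; s < S.n_slices; s++)
    S.ogr_in_slice[s] = ogs[s] == NA_INTEGER ? -1 : ogs[s] - 1;
  S.dist.assign(S.n, std::vector<int>(S.n));
  for (int i = 0; i < S.n; i++)
    for (int j = 0; j < S.n; j++) S.dist[i][j] = dm(i, j);
  return S;
}

static GTree unpack_gtree(const List &g) {
  GTree G;
  List ch = g["children"];
  IntegerVector ord = g["order"];
  IntegerVector lt = g["leaf_tube"];
  G.n = ch.size();
  G.root = as<int>(g["root"]) - 1;
  G.children.resize(G.n);
  for (int i = 0; i < G.n; i++) {
    IntegerVector c = ch[i];
    for (int j = 0; j < c.size(); j++) G.children[i].push_back(c[j] - 1);
  }
  G.order.resize(ord.size());
  for (int i = 0; i < ord.size(); i++) G.order[i] = ord[i] - 1;
  G.leaf_tube.resize(G.n);
  for (int i = 0; i < G.n; i++)
    G.leaf_tube[i] = (lt[i] == NA_INTEGER || lt[i] == 0) ? -1 : lt[i] - 1;
  return G;
}

// Donor-tube minimization with (cost, distance-to-d, enumeration order)
// tie-breaking; candidates must be offered in enumeration order.
struct Best {
  double cost;
  int dist, id, id2;
  Best() : cost(INF), dist(0), id(-1), id2(-1) {}
  void offer(double c, int dst, int i, int i2 = -1) {
    if (c < cost || (c == cost && dst < dist)) {
      cost = c; dist = dst; id = i; id2 = i2;
    }
  }
};

class DP {
public:
  const STree &S;
  const GTree &G;
  Costs cc;
  int E, D;
  std::vector<double> cmin;           // E*D overall minima
  std::vector<double> noout, outv;    // per edge, defined at d0
  std::vector<double> rowcost;        // 35*D*E (i fastest), if full
  std::vector<int> rpar1, rpar2;
  bool full;

  DP(const STree &S_, const GTree &G_, const Costs &cc_, bool full_)
    : S(S_), G(G_), cc(cc_), E(G_.n), D(S_.n), full(full_) {
    cmin.assign((size_t)E * D, INF);
    noout.assign(E, INF);
    outv.assign(E, INF);
    if (full) {
      rowcost.assign((size_t)E * D * 35, INF);
      rpar1.assign((size_t)E * D * 35, -1);
      rpar2.assign((size_t)E * D * 35, -1);
    }
  }

  double C(int e, int d) const { return cmin[(size_t)e * D + d]; }
  size_t idx(int e, int d, int i) const {
    return ((size_t)e * D + d) * 35 + i;
  }

  void run() {
    std::vector<int> ord_plain, ord_e0;   // slices deep to shallow
    for (int s = S.n_slices - 1; s >= 0; s--) {
      int og = S.ogr_in_slice[s];
      if (og >= 0) ord_plain.push_back(og);
      for (size_t j = 0; j < S.slices[s].size(); j++) {
        int d = S.slices[s][j];
        if (d != og) { ord_plain.push_back(d); ord_e0.push_back(d); }
      }
      if (og >= 0) ord_e0.push_back(og);
    }
    for (size_t k = 0; k < G.order.size(); k++) {
      int e = G.order[k];
      const std::vector<int> &ord = (e == G.root) ? ord_e0 : ord_plain;
      for (size_t t = 0; t < ord.size(); t++) cell(e, ord[t]);
    }
  }

  void cell(int e, int d) {
    double row[35];
    int p1[35], p2[35];
    for (int i = 0; i < 35; i++) { row[i] = INF; p1[i] = -1; p2[i] = -1; }

    bool leafE = G.children[e].empty();
    bool bifE = G.children[e].size() == 2;
    int e1 = bifE ? G.children[e][0] : -1;
    int e2 = bifE ? G.children[e][1] : -1;
    bool isE0 = e == G.root;
    bool isD0 = d == S.d0;
    bool isOgr = S.ogr[d];
    bool term = S.term[d];
    int nchD = (int)S.children[d].size();
    int d1 = nchD >= 1 ? S.children[d][0] : -1;
    int d2 = nchD >= 2 ? S.children[d][1] : -1;
    int slice = S.slice[d] - 1;

    // rows 0-2: leaf edges at terminal tubes
    if (leafE && term) {
      if (d == G.leaf_tube[e]) row[0] = 0.0;
      else if (!isOgr) row[1] = cc.tr_without;
      else row[2] = cc.gain;
    }
    // row 3: pass into the single child tube of the next slice
    if (nchD == 1) row[3] = C(e, d1);
    // rows 4-5: speciation forks (also used at d0)
    if (bifE && nchD == 2) {
      row[4] = C(e1, d1) + C(e2, d2);
      row[5] = C(e2, d1) + C(e1, d2);
    }
    // rows 6-7: speciation with a loss on one side
    if (!isD0 && nchD == 2) {
      row[6] = C(e, d1) + cc.loss;
      row[7] = C(e, d2) + cc.loss;
    }
    // rows 8-11: root tube, gene present (nout) or absent (out) in root
    if (isD0 && nchD == 2) {
      bool og1 = S.ogr[d1], og2 = S.ogr[d2];
      if (!og1 && og2) { row[8] = C(e, d1); row[11] = C(e, d2); }
      if (og1 && !og2) { row[9] = C(e, d2); row[10] = C(e, d1); }
    }
    // row 12: duplication (at d0 neither copy may exit through out rows)
    if (bifE && !isOgr) {
      row[12] = isD0 ? noout[e1] + noout[e2] + cc.dupl
                     : C(e1, d) + C(e2, d) + cc.dupl;
    }
    // row 13: free root duplication, at least one copy exits
    if (bifE && isD0) {
      double v1 = outv[e1] + C(e2, d);
      double v2 = C(e1, d) + outv[e2];
      if (v1 <= v2) { row[13] = v1; p1[13] = 0; }
      else { row[13] = v2; p1[13] = 1; }
    }
    // row 14: free duplication in the outgroup
    if (bifE && isOgr) row[14] = C(e1, d) + C(e2, d);
    // rows 15-18: transfer with retention / gain of one copy
    if (bifE && (isOgr || !isD0)) {
      Best bL, bR;
      const std::vector<int> &ss = S.slices[slice];
      for (size_t j = 0; j < ss.size(); j++) {
        int dp = ss[j];
        if (dp == d || S.ogr[dp]) continue;
        double extra = isOgr ? cc.gain : cc.tr_with;
        bL.offer(C(e1, dp) + C(e2, d) + extra, S.dist[d][dp], dp);
        bR.offer(C(e2, dp) + C(e1, d) + extra, S.dist[d][dp], dp);
      }
      int iL = isOgr ? 17 : 15, iR = isOgr ? 18 : 16;
      if (bL.id >= 0) { row[iL] = bL.cost; p1[iL] = bL.id; }
      if (bR.id >= 0) { row[iR] = bR.cost; p1[iR] = bR.id; }
    }
    // row 19: the gene goes dormant into the outgroup of its slice
    if (!isE0 && !isOgr && !isD0 && !term) {
      int og = S.ogr_in_slice[slice];
      if (og >= 0) { row[19] = C(e, og) + cc.sleep; p1[19] = og; }
    }
    // row 20: origin of the common ancestor of the whole family
    if (isE0 && isOgr) {
      Best b;
      const std::vector<int> &ss = S.slices[slice];
      for (size_t j = 0; j < ss.size(); j++) {
        int dp = ss[j];
        if (dp == d || S.ogr[dp]) continue;
        b.offer(C(e, dp) + cc.gain_big, S.dist[d][dp], dp);
      }
      if (b.id >= 0) { row[20] = b.cost; p1[20] = b.id; }
    }
    // rows 21-34: events routed through a same-slice donor tube d'
    bool trRows = !isOgr && !isD0;        // transfer-without-retention rows
    bool gaRows = isOgr && !isE0;         // gain rows (from the outgroup)
    if (trRows || gaRows) {
      double enter = trRows ? cc.tr_without : cc.gain;
      int iPass = trRows ? 21 : 22;
      int iLR = trRows ? 23 : 25, iRL = trRows ? 24 : 26;
      int iL = trRows ? 27 : 29, iR = trRows ? 28 : 30;
      int iDup = trRows ? 31 : 32;
      int iDbl = trRows ? 33 : 34;
      // row 21 has no e != e0 condition, row 22 does (checked via gaRows)
      Best bPass, bLR, bRL, bLo, bRo, bDup;
      const std::vector<int> &ss = S.slices[slice];
      for (size_t j = 0; j < ss.size(); j++) {
        int dp = ss[j];
        if (dp == d || S.ogr[dp]) continue;
        int dst = S.dist[d][dp];
        int nc = (int)S.children[dp].size();
        if (nc == 1) {
          bPass.offer(C(e, S.children[dp][0]) + enter, dst, dp);
        } else if (nc == 2) {
          int c1 = S.children[dp][0], c2 = S.children[dp][1];
          if (bifE) {
            bLR.offer(C(e1, c1) + C(e2, c2) + enter, dst, dp);
            bRL.offer(C(e1, c2) + C(e2, c1) + enter, dst, dp);
          }
          bLo.offer(C(e, c1) + enter + cc.loss, dst, dp);
          bRo.offer(C(e, c2) + enter + cc.loss, dst, dp);
        }
        if (bifE)
          bDup.offer(C(e1, dp) + C(e2, dp) + enter + cc.dupl, dst, dp);
      }
      if (bPass.id >= 0) { row[iPass] = bPass.cost; p1[iPass] = bPass.id; }
      if (bLR.id >= 0) { row[iLR] = bLR.cost; p1[iLR] = bLR.id; }
      if (bRL.id >= 0) { row[iRL] = bRL.cost; p1[iRL] = bRL.id; }
      if (bLo.id >= 0) { row[iL] = bLo.cost; p1[iL] = bLo.id; }
      if (bRo.id >= 0) { row[iR] = bRo.cost; p1[iR] = bRo.id; }
      if (bDup.id >= 0) { row[iDup] = bDup.cost; p1[iDup] = bDup.id; }
      if (bifE) {
        Best bDbl;
        double extra2 = trRows ? cc.tr_without + cc.tr_with
                               : cc.gain + cc.tr_with;
        for (size_t j = 0; j < ss.size(); j++) {
          int dp = ss[j];
          if (dp == d || S.ogr[dp]) continue;
          for (size_t j2 = 0; j2 < ss.size(); j2++) {
            int dq = ss[j2];
            if (dq == d || dq == dp || S.ogr[dq]) continue;
            bDbl.offer(C(e1, dp) + C(e2, dq) + extra2,
                       S.dist[d][dp] + S.dist[d][dq], dp, dq);
          }
        }
        if (bDbl.id >= 0) {
          row[iDbl] = bDbl.cost; p1[iDbl] = bDbl.id; p2[iDbl] = bDbl.id2;
        }
      }
    }

    double best = INF;
    for (int i = 0; i < 35; i++) if (row[i] < best) best = row[i];
    cmin[(size_t)e * D + d] = best;
    if (isD0) {
      double n = INF, o = INF;
      for (int i = 0; i < 35; i++) {
        if (i == 10 || i == 11) { if (row[i] < o) o = row[i]; }
        else if (row[i] < n) n = row[i];
      }
      noout[e] = n;
      outv[e] = o;
    }
    if (full) {
      for (int i = 0; i < 35; i++) {
        rowcost[idx(e, d, i)] = row[i];
        rpar1[idx(e, d, i)] = p1[i];
        rpar2[idx(e, d, i)] = p2[i];
      }
    }
  }
};

static Costs unpack_costs(const NumericVector &v) {
  Costs c;
  c.loss = v["loss"]; c.dupl = v["dupl"]; c.gain = v["gain"];
  c.tr_with = v["tr_with"]; c.tr_without = v["tr_without"];
  c.sleep = v["sleep"]; c.gain_big = v["gain_big"];
  return c;
}

// [[Rcpp::export]]
List cpp_reconcile(List gene, List s0, NumericVector costs, bool full) {
  STree S = unpack_stree(s0);
  GTree G = unpack_gtree(gene);
  Costs cc = unpack_costs(costs);
  DP dp(S, G, cc, full);
  dp.run();
  List out = List::create(_["cost"] = dp.C(G.root, S.d0));
  NumericMatrix cm(dp.E, dp.D);
  for (int e = 0; e < dp.E; e++)
    for (int d = 0; d < dp.D; d++) cm(e, d) = dp.C(e, d);
  out["cmin"] = cm;
  if (full) {
    NumericVector rc(dp.rowcost.begin(), dp.rowcost.end());
    IntegerVector q1(dp.rpar1.size()), q2(dp.rpar2.size());
    for (size_t k = 0; k < dp.rpar1.size(); k++) {
      // row 13's parameter becomes a variant number (1/2), not a tube id
      q1[k] = dp.rpar1[k] < 0 ? NA_INTEGER : dp.rpar1[k] + 1;
      q2[k] = dp.rpar2[k] < 0 ? NA_INTEGER : dp.rpar2[k] + 1;
    }
    rc.attr("dim") = Dimension(35, dp.D, dp.E);
    q1.attr("dim") = Dimension(35, dp.D, dp.E);
    q2.attr("dim") = Dimension(35, dp.D, dp.E);
    out["rowcost"] = rc;
    out["par1"] = q1;
    out["par2"] = q2;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_total_costs(List genes, List s0, NumericVector costs) {
  STree S = unpack_stree(s0);
  Costs cc = unpack_costs(costs);
  int n = genes.size();
  NumericVector out(n);
  for (int j = 0; j < n; j++) {
    GTree G = unpack_gtree(genes[j]);
    DP dp(S, G, cc, false);
    dp.run();
    out[j] = dp.C(G.root, S.d0);
  }
  return out;
}
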