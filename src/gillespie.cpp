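#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Agent-based Gillespie simulation of the two reversible fission-fusion
// reactions on N unit edges:
//
//   X1 + X1 <-> X2   (tip-to-tip, rates a1 / b1)
//   X1 + X2 <-> X3   (tip-to-side, rates a2 / b2)
//
// State: 2N tips, each assigned to exactly one node; a node holds 1-3 tips
// (degree 1-3).  Degree-4 nodes are excluded by construction.  Fusion
// propensities carry a convention multiplier (tt_scale, ts_scale) on top of
// the textbook pairwise mass-action form; see the R-level documentation.
//
// Uses R's RNG (unif_rand / exp_rand) so set.seed() controls the run.

namespace {

struct DegreeLists {
    // nodes indexed 0 .. 2N-1; slot reuse via free stack
    std::vector<int> list1, list2, list3;
    std::vector<int> pos;  // position of node in its degree list
    std::vector<int>* lst(int deg) {
        return deg == 1 ? &list1 : (deg == 2 ? &list2 : &list3);
    }
    void add(int node, int deg) {
        std::vector<int>* L = lst(deg);
        pos[node] = (int)L->size();
        L->push_back(node);
    }
    void remove(int node, int deg) {
        std::vector<int>* L = lst(deg);
        int p = pos[node];
        int last = L->back();
        (*L)[p] = last;
        pos[last] = p;
        L->pop_back();
    }
    int sample(int deg) {
        std::vector<int>* L = lst(deg);
        int i = (int)(unif_rand() * L->size());
        if (i >= (int)L->size()) i = (int)L->size() - 1;
        return (*L)[i];
    }
};

}  // namespace

// [[Rcpp::export]]
List ff_gillespie_cpp(int N, double a1, double b1, double a2, double b2,
                      double tt_scale, double ts_scale,
                      int n_events, int record_every) {
    if (N < 1) stop("N must be >= 1");
    const int ntips = 2 * N;

    std::vector<int> node_of_tip(ntips);
    std::vector<int> tips(3 * ntips);  // up to 3 tips per node slot
    std::vector<int> deg(ntips, 0);
    std::vector<int> free_nodes;
    DegreeLists dl;
    dl.pos.assign(ntips, -1);

    for (int t = 0; t < ntips; ++t) {  // every tip its own degree-1 node
        node_of_tip[t] = t;
        tips[3 * t] = t;
        deg[t] = 1;
        dl.add(t, 1);
    }

    int nrec = (record_every > 0) ? (n_events / record_every + 1) : 1;
    IntegerMatrix traj(nrec, 4);  // event, X1, X2, X3
    NumericVector traj_time(nrec);
    int irec = 0;
    bool absorbed = false;
    double time = 0.0;
    int ev = 0;

    auto record = [&](int at_event) {
        if (irec < nrec) {
            traj(irec, 0) = at_event;
            traj(irec, 1) = (int)dl.list1.size();
            traj(irec, 2) = (int)dl.list2.size();
            traj(irec, 3) = (int)dl.list3.size();
            traj_time[irec] = time;
            ++irec;
        }
    };
    if (record_every > 0) record(0);

    // remove tip `t` (position k) from node `u` of degree d (d>=2)
    auto detach_tip = [&](int u, int k, int d) {
        for (int j = k; j < d - 1; ++j) tips[3 * u + j] = tips[3 * u + j + 1];
        deg[u] = d - 1;
    };

    for (ev = 1; ev <= n_events; ++ev) {
        double X1 = (double)dl.list1.size();
        double X2 = (double)dl.list2.size();
        double X3 = (double)dl.list3.size();

        double p1 = tt_scale * a1 * X1 * (X1 - 1.0) / 2.0;  // tt fusion
        double p2 = b1 * X2;                                // tt fission
        double p3 = ts_scale * a2 * X1 * X2;                // ts fusion
        double p4 = b2 * X3;                                // ts fission
        double total = p1 + p2 + p3 + p4;
        if (total <= 0.0) { absorbed = true; break; }

        time += exp_rand() / total;
        double u = unif_rand() * total;

        if (u < p1) {
            // tip-to-tip fusion: two distinct X1 nodes merge into one X2
            int n1 = (int)dl.list1.size();
            int i = (int)(unif_rand() * n1); if (i >= n1) i = n1 - 1;
            int j = (int)(unif_rand() * (n1 - 1)); if (j >= n1 - 1) j = n1 - 2;
            if (j >= i) ++j;
            int a = dl.list1[i], b = dl.list1[j];
            int tb = tips[3 * b];
            dl.remove(a, 1); dl.remove(b, 1);
            tips[3 * a + 1] = tb;
            node_of_tip[tb] = a;
            deg[a] = 2; deg[b] = 0;
            free_nodes.push_back(b);
            dl.add(a, 2);
        } else if (u < p1 + p2) {
            // tip-to-tip fission: X2 splits into two X1
            int a = dl.sample(2);
            int t1 = tips[3 * a + 1];
            dl.remove(a, 2);
            deg[a] = 1;
            int b = free_nodes.back(); free_nodes.pop_back();
            tips[3 * b] = t1;
            node_of_tip[t1] = b;
            deg[b] = 1;
            dl.add(a, 1); dl.add(b, 1);
        } else if (u < p1 + p2 + p3) {
            // tip-to-side fusion: X1 + X2 -> X3
            int a = dl.sample(1);
            int b = dl.sample(2);
            int ta = tips[3 * a];
            dl.remove(a, 1); dl.remove(b, 2);
            tips[3 * b + 2] = ta;
            node_of_tip[ta] = b;
            deg[b] = 3; deg[a] = 0;
            free_nodes.push_back(a);
            dl.add(b, 3);
        } else {
            // tip-to-side fission: X3 -> X1 + X2, detached tip uniform of 3
            int a = dl.sample(3);
            int k = (int)(unif_rand() * 3.0); if (k > 2) k = 2;
            int tk = tips[3 * a + k];
            dl.remove(a, 3);
            detach_tip(a, k, 3);
            int b = free_nodes.back(); free_nodes.pop_back();
            tips[3 * b] = tk;
            node_of_tip[tk] = b;
            deg[b] = 1;
            dl.add(a, 2); dl.add(b, 1);
        }

        // mass conservation: X1 + 2 X2 + 3 X3 == 2N, cheap invariant check
        if ((int)(dl.list1.size() + 2 * dl.list2.size() + 3 * dl.list3.size())
            != ntips)
            stop("internal error: tip conservation violated");

        if (record_every > 0 && ev % record_every == 0) record(ev);
    }
    if (ev > n_events) ev = n_events;

    IntegerVector not1(ntips);
    for (int t = 0; t < ntips; ++t) not1[t] = node_of_tip[t] + 1;

    return List::create(
        _["node_of_tip"] = not1,
        _["X1"] = (int)dl.list1.size(),
        _["X2"] = (int)dl.list2.size(),
        _["X3"] = (int)dl.list3.size(),
        _["time"] = time,
        _["events"] = absorbed ? ev - 1 : ev,
        _["absorbed"] = absorbed,
        _["traj"] = traj(Range(0, irec > 0 ? irec - 1 : 0), _),
        _["traj_time"] = traj_time[Range(0, irec > 0 ? irec - 1 : 0)]);
}
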