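step,partition,cluster_a,cluster_b,delta,mean_nmi_after
1,km,a1,a2,0.100900784129521,0.894284657813905
2,km,c1,c2,0.113802374304719,0.932218782582145
3,hc,v1,v2,0.110973486164142,0.969209944636859
4,hc,x1,x2,0.0923701660894224,1
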