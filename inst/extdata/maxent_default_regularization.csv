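class,n,s
linear,0,1.0
linear,10,1.0
linear,30,0.2
linear,100,0.05
quadratic,0,1.3
quadratic,10,0.8
quadratic,17,0.5
quadratic,30,0.25
quadratic,100,0.05
product,0,2.6
product,10,1.6
product,17,0.9
product,30,0.55
product,100,0.05
hinge,0,0.5
hinge,1,0.5
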