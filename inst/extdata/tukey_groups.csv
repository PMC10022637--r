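group,value
ctrl,1.0968
ctrl,-0.4518
ctrl,0.2905
ctrl,0.5063
ctrl,0.3234
ctrl,-0.0849
ctrl,1.2092
ctrl,-0.0757
low,2.6147
low,0.9498
low,2.0439
low,2.8293
low,-0.1111
low,0.777
low,0.8933
low,1.5088
low,0.7726
low,-1.1252
mid,-0.6524
mid,2.3561
mid,1.0547
mid,-0.125
mid,1.1625
mid,2.2717
high,4.7162
high,2.8556
high,2.9942
high,1.7895
high,3.5681
high,2.688
high,3.5644
high,3.7639
high,4.0281
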